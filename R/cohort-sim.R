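#' Simulate a full study cohort of repeat-scan angiograms
#'
#' Emulates the study's acquisition design for `n_participants`
#' participants: per participant and per plexus (two independent vessel
#' trees stand in for the superficial and deep capillary plexuses), a base
#' angiogram is re-acquired three times — scan 1 by observer 1 under the
#' `inter` perturbation model, scans 2 and 3 by observer 2 under the
#' `intra` model. Each scan draws its own perturbation realisation
#' (translation direction uniform on the circle at the model's shift
#' magnitude, fresh noise) so repeat scans differ, while intra-observer
#' scans stay closer to each other than the inter-observer scan whenever
#' the intra magnitude is the smaller one.
#'
#' @param n_participants number of participants (>= 1).
#' @param vessel a [vessel_tree_params()] shared by all trees.
#' @param intra,inter [scan_perturbation()] magnitude templates for
#'   same-observer and between-observer re-acquisition; the inter
#'   magnitude must be at least the intra magnitude.
#' @param seed integer RNG master seed; per-image seeds are derived from
#'   it, so the cohort is bit-reproducible.
#' @return list with `images` (named list of intensity matrices, one per
#'   participant x scan x plexus) and `metadata` (data frame with columns
#'   `participant_id`, `birth_year`, `observer_id`, `scan_index`,
#'   `plexus`, `eye`, `signal_strength`, `artefact_flag`, `image_key`).
#' @export
generate_cohort <- function(n_participants = 43L,
                            vessel = vessel_tree_params(),
                            intra = scan_perturbation(shift_px = c(0.5, 0),
                                                      noise_reseed = TRUE,
                                                      extra_noise_sd = 0.01),
                            inter = scan_perturbation(shift_px = c(3, 0),
                                                      noise_reseed = TRUE,
                                                      gamma = 1.05,
                                                      extra_noise_sd = 0.03),
                            seed = 1L) {
  if (n_participants < 1L) stop_config("n_participants must be >= 1")
  if (perturbation_magnitude(inter) < perturbation_magnitude(intra))
    stop_config("inter perturbation magnitude must be >= intra magnitude")
  design <- study_design()
  plexuses <- c("SCP", "DCP")
  images <- list()
  meta <- list()
  # independent sub-seeds per (participant, plexus, scan), derived from the
  # master seed; kept below 2^31
  base_seed <- (as.integer(seed) %% 100000L) * 10000L
  with_seed(seed, {
    birth_years <- sample(1966:1999, n_participants, replace = TRUE)
    shift_angles <- matrix(runif(n_participants * 6, 0, 2 * pi),
                           n_participants)
  })
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%03d", i)
    eye <- if (birth_years[i] %% 2L == 0L) "right" else "left"
    for (pl in seq_along(plexuses)) {
      plx <- plexuses[pl]
      tree_seed <- base_seed + i * 100L + pl * 10L
      base <- generate_vessel_tree(vessel, seed = tree_seed)
      for (s in 1:3) {
        template <- if (s == 1L) inter else intra
        mag <- sqrt(sum(template$shift_px^2))
        ang <- shift_angles[i, (pl - 1L) * 3L + s]
        p <- scan_perturbation(shift_px = mag * c(cos(ang), sin(ang)),
                               noise_reseed = template$noise_reseed,
                               gamma = template$gamma,
                               extra_noise_sd = template$extra_noise_sd)
        img <- perturb_scan(base, p, seed = tree_seed + s)
        key <- sprintf("%s_scan%d_%s", pid, s, plx)
        images[[key]] <- img
        meta[[length(meta) + 1L]] <-
          data.frame(participant_id = pid, birth_year = birth_years[i],
                     observer_id = unname(design$observer_of_scan[as.character(s)]),
                     scan_index = s, plexus = plx, eye = eye,
                     signal_strength = 10L, artefact_flag = FALSE,
                     image_key = key)
      }
    }
  }
  list(images = images, metadata = do.call(rbind, meta))
}
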