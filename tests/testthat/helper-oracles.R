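# Independent brute-force oracles. These deliberately re-derive, by direct
# enumeration, quantities the package computes by faster routes; they must
# never call the implementation they check.

# evaluate expr under a local seed without clobbering the session RNG
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# occupied-box count by scanning every grid cell with any()
brute_box_count <- function(mat, s) {
  H <- nrow(mat); W <- ncol(mat)
  n <- 0L
  for (r0 in seq(1, H, by = s)) {
    for (c0 in seq(1, W, by = s)) {
      blk <- mat[r0:min(H, r0 + s - 1), c0:min(W, c0 + s - 1), drop = FALSE]
      if (any(blk == 1)) n <- n + 1L
    }
  }
  n
}

# ANOVA mean squares of an n x k table by explicit double loops
brute_mean_squares <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  g <- mean(Y)
  ssr <- ssc <- sse <- ssw <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(Y[i, ]) - g)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(Y[, j]) - g)^2
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + g)^2
      ssw <- ssw + (Y[i, j] - mean(Y[i, ]))^2
    }
  }
  list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
       MSE = sse / ((n - 1) * (k - 1)), MSW = ssw / (n * (k - 1)))
}

# single-measure Shrout-Fleiss point estimates straight from the formulas
brute_icc <- function(Y, model) {
  ms <- brute_mean_squares(Y)
  n <- nrow(Y); k <- ncol(Y)
  switch(model,
         ICC_1_1 = (ms$MSR - ms$MSW) / (ms$MSR + (k - 1) * ms$MSW),
         ICC_2_1 = (ms$MSR - ms$MSE) /
           (ms$MSR + (k - 1) * ms$MSE + k * (ms$MSC - ms$MSE) / n),
         ICC_3_1 = (ms$MSR - ms$MSE) / (ms$MSR + (k - 1) * ms$MSE))
}

# TRUE if any 2x2 block of the 0/1 matrix is fully foreground
has_2x2_block <- function(mat) {
  H <- nrow(mat); W <- ncol(mat)
  if (H < 2 || W < 2) return(FALSE)
  s <- mat[-H, -W] + mat[-H, -1] + mat[-1, -W] + mat[-1, -1]
  any(s == 4)
}

# foreground pixel count of Pascal's triangle mod 2 at a given depth,
# by actually building the triangle row by row
brute_pascal_mod2_count <- function(depth) {
  size <- 2^depth
  row <- 1L
  total <- 0L
  for (i in seq_len(size)) {
    total <- total + sum(row %% 2L == 1L)
    row <- c(row, 0L) + c(0L, row)
    row <- row %% 2L  # keep integers small
  }
  total
}
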