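# Small fixtures shared across test files; everything is generated in code.

# A tiny stack + sharp virtual species + training table, cheap enough for
# model unit tests.
tiny_setup <- function(seed = 1, n = 40, n_presences = 120, n_pa = 500,
                       prevalence = 0.15) {
  stack <- make_climate_stack(seed, n_layers = 4, n_rows = n, n_cols = n,
                              autocorr_range_cells = 5, collinear_pairs = 0)
  species <- virtual_species(list(bio1 = c(0, -30), bio12 = c(0, -30)),
                             prevalence_target = prevalence)
  species <- freeze_intercept(stack, species)
  truth <- true_suitability(stack, species)
  occs <- sample_occurrences(truth, n_presences, seed + 100)
  pa <- sample_pseudo_absences(stack, n_pa, seed + 200)
  table <- build_training_table(extract_values(stack, occs),
                                extract_values(stack, pa))
  list(stack = stack, species = species, truth = truth, occs = occs,
       table = table)
}

# Linearly separable toy table on one predictor.
separable_table <- function(n_each = 20) {
  build_training_table(
    data.frame(bio1 = seq(2, 3, length.out = n_each),
               bio12 = seq(2, 3, length.out = n_each)),
    data.frame(bio1 = seq(-3, -2, length.out = n_each),
               bio12 = seq(-3, -2, length.out = n_each)))
}

# Binary range wrapper around a logical matrix on a trivial georeference.
as_range <- function(m, threshold = 0.5) {
  binarize(raster_grid(matrix(as.numeric(m), nrow(m), ncol(m))), threshold)
}

# Brute-force flood fill used as the patch-labelling oracle.
flood_fill_patches <- function(v, queen = FALSE) {
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(0L, nr, nc)
  np <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!v[r0, c0] || lab[r0, c0] != 0L) next
    np <- np + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- np
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
      if (queen) { dr <- c(dr, -1, -1, 1, 1); dc <- c(dc, -1, 1, -1, 1) }
      for (k in seq_along(dr)) {
        r <- cur[1L] + dr[k]; c <- cur[2L] + dc[k]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && v[r, c] &&
            lab[r, c] == 0L) {
          lab[r, c] <- np
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Independent AI computation: direct edge enumeration + the g_max formula.
ai_oracle <- function(v) {
  a <- sum(v)
  g <- 0L
  nr <- nrow(v); nc <- ncol(v)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!v[r, c]) next
    if (r < nr && v[r + 1L, c]) g <- g + 1L
    if (c < nc && v[r, c + 1L]) g <- g + 1L
  }
  n <- floor(sqrt(a)); m <- a - n^2
  gmax <- if (m == 0) 2 * n * (n - 1) else if (m <= n)
    2 * n * (n - 1) + 2 * m - 1 else 2 * n * (n - 1) + 2 * m - 2
  if (gmax == 0) NA_real_ else 100 * g / gmax
}

# Independent AUC: exhaustive pairwise Mann-Whitney counting.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Independent VIF via an explicit normal-equations solve.
vif_oracle <- function(x) {
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    a <- cbind(1, x[, -j, drop = FALSE])
    beta <- solve(t(a) %*% a, t(a) %*% x[, j])
    res <- x[, j] - a %*% beta
    r2 <- 1 - sum(res^2) / sum((x[, j] - mean(x[, j]))^2)
    out[j] <- 1 / (1 - r2)
  }
  names(out) <- colnames(x)
  out
}
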