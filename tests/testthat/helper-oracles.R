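# Independent reference implementations used as oracles. These are written
# as direct transliterations of the defining formulas, deliberately kept
# separate from (and simpler than) the package code paths they check.

# bias score: plain transliteration of the implicit-wanting formula block,
# both IW terms coded independently, zero-win terms dropped
oracle_bias <- function(win_sed, win_pa, rt_all, rt_sed, rt_pa, n) {
  t_sed <- if (win_sed > 0) win_sed * (rt_all / rt_sed) else 0
  t_pa <- if (win_pa > 0) win_pa * (rt_all / rt_pa) else 0
  iw_sed <- t_sed - t_pa
  iw_pa <- t_pa - t_sed
  raw <- iw_sed - iw_pa
  bias <- raw * 100 / (2 * n)
  list(iw_sed = iw_sed, iw_pa = iw_pa, raw = raw,
       bias = max(-100, min(100, bias)))
}

# Pearson r via the raw covariance formula, p via the t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# partial correlation via explicit projection matrices
oracle_partial <- function(x, y, Z) {
  Z <- cbind(1, as.matrix(Z))
  P <- diag(length(x)) - Z %*% solve(t(Z) %*% Z) %*% t(Z)
  rx <- drop(P %*% x)
  ry <- drop(P %*% y)
  oracle_pearson(rx, ry)$r
}

# single-measure absolute-agreement ICC from an aov() two-way decomposition
oracle_icc <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  long <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), k)),
    session = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(y ~ subject + session, data = long))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["session", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# pooled-variance t statistic from the textbook formula
oracle_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# small two-category catalog for cheap scoring tests
toy_catalog <- function(n_sed = 2, n_pa = 2) {
  tibble::tibble(
    id = c(paste0("sed", seq_len(n_sed)), paste0("pa", seq_len(n_pa))),
    label = id,
    category = rep(c("SEDENTARY", "PHYSICAL"), c(n_sed, n_pa))
  )
}

# deterministic cross-trial log: n_sed sedentary wins at rt_sed seconds,
# n_pa physical wins at rt_pa, spread over the 64 cross pairs
cross_log <- function(pairs, n_sed, n_pa, rt_sed = 1, rt_pa = 1,
                      catalog = apa_catalog()) {
  cross <- pairs[pairs$pair_type == "CROSS", ]
  stopifnot(n_sed + n_pa <= nrow(cross))
  cross <- cross[seq_len(n_sed + n_pa), ]
  cat_of <- stats::setNames(catalog$category, catalog$id)
  sed_member <- ifelse(cat_of[cross$left_id] == "SEDENTARY",
                       cross$left_id, cross$right_id)
  pa_member <- ifelse(cat_of[cross$left_id] == "SEDENTARY",
                      cross$right_id, cross$left_id)
  pick_sed <- seq_len(n_sed + n_pa) <= n_sed
  tibble::tibble(
    pair_id = cross$pair_id,
    chosen_id = ifelse(pick_sed, sed_member, pa_member),
    rt = ifelse(pick_sed, rt_sed, rt_pa),
    responded = TRUE
  )
}
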