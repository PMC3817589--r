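# Internal helpers shared across modules.

# Beta draw parameterised by mean and concentration (shape1 + shape2).
rbeta_mc <- function(n, mean, conc) {
  stats::rbeta(n, shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

# Normal draw truncated to strictly positive values, by rejection.
rnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

# Nearest-record join of CTD parameters onto frame depths, per site.
# `ctd` must contain site, depth_m and the requested parameter columns.
nearest_ctd <- function(frame_site, frame_depth, ctd,
                        params = c("salinity", "temperature_C", "pH",
                                   "oxygen_umol_l", "fluorescence")) {
  params <- intersect(params, names(ctd))
  out <- matrix(NA_real_, nrow = length(frame_depth), ncol = length(params),
                dimnames = list(NULL, params))
  for (s in unique(frame_site)) {
    rows <- which(frame_site == s)
    sub <- ctd[ctd$site == s, , drop = FALSE]
    if (nrow(sub) == 0) next
    ord <- order(sub$depth_m)
    d <- sub$depth_m[ord]
    # index of nearest depth for each frame
    lo <- findInterval(frame_depth[rows], d, all.inside = TRUE)
    hi <- pmin(lo + 1, length(d))
    pick <- ifelse(abs(frame_depth[rows] - d[lo]) <=
                     abs(d[hi] - frame_depth[rows]), lo, hi)
    for (p in params) out[rows, p] <- sub[[p]][ord][pick]
  }
  tibble::as_tibble(out)
}

stop_not_df <- function(x, arg) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame, not %s.", arg, class(x)[1]))
  }
}

require_cols <- function(df, cols, arg) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  arg, paste(miss, collapse = ", ")))
  }
}
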