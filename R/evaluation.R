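#' Location error between estimated and reference tumor positions
#'
#' Signed per-axis differences `est - ref` along left-right (x),
#' anterior-posterior (y) and superior-inferior (z), and their Euclidean
#' norm, all in mm.
#'
#' @param est,ref numeric length-3 world coordinates (mm).
#' @param case,fraction,mode optional identifiers copied into the record.
#' @return a one-row data.frame with columns `case`, `fraction`, `mode`,
#'   `err_lr_mm`, `err_ap_mm`, `err_si_mm`, `err_euclid_mm`.
#' @export
location_error <- function(est, ref, case = NA, fraction = NA, mode = NA) {
  est <- as.numeric(est); ref <- as.numeric(ref)
  if (length(est) != 3L || length(ref) != 3L ||
      any(!is.finite(est)) || any(!is.finite(ref)))
    stop("`est` and `ref` must be finite length-3 coordinates")
  d <- est - ref
  data.frame(case = case, fraction = fraction, mode = mode,
             err_lr_mm = d[1], err_ap_mm = d[2], err_si_mm = d[3],
             err_euclid_mm = sqrt(sum(d^2)))
}

#' Pooled-variance two-sample Student t-test
#'
#' Equal-variance Student t statistic with `n_a + n_b - 2` degrees of freedom
#' and a two-sided p-value, used to compare mean location errors across
#' template modes.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `t`, `dof`, `p`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per sample")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate input: zero pooled variance")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-sided F-test for equality of variances
#'
#' `F = s_a^2 / s_b^2` with `(n_a - 1, n_b - 1)` degrees of freedom, used to
#' compare the precision (standard deviation of location errors) across
#' template modes.
#'
#' @param a,b numeric samples, each of length >= 2 with positive variance.
#' @return list with `F`, `dof1`, `dof2`, `p`.
#' @export
variance_f_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per sample")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("degenerate input: zero variance")
  ht <- stats::var.test(a, b)
  list(F = unname(ht$statistic), dof1 = unname(ht$parameter[1]),
       dof2 = unname(ht$parameter[2]), p = ht$p.value)
}

#' Summarize location-error records across template modes
#'
#' Per-mode mean and sample standard deviation (n-1 denominator) of each
#' axis error and the Euclidean distance, plus pairwise pooled t-tests
#' (means) and F-tests (variances) of the Euclidean errors across modes.
#'
#' @param records data.frame of [location_error()] rows.
#' @return list with data.frames `per_mode` and `pairwise`.
#' @export
summarize_errors <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  metrics <- c("err_lr_mm", "err_ap_mm", "err_si_mm", "err_euclid_mm")
  modes <- unique(as.character(records$mode))
  per_mode <- do.call(rbind, lapply(modes, function(m) {
    sub <- records[records$mode == m, , drop = FALSE]
    row <- data.frame(mode = m, n = nrow(sub))
    for (mc in metrics) {
      row[[paste0("mean_", mc)]] <- mean(sub[[mc]])
      row[[paste0("sd_", mc)]] <-
        if (nrow(sub) > 1L) stats::sd(sub[[mc]]) else 0
    }
    row$n1_flag <- nrow(sub) == 1L
    row
  }))
  pairwise <- NULL
  if (length(modes) >= 2L) {
    combs <- utils::combn(modes, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      m1 <- combs[1, i]; m2 <- combs[2, i]
      a <- records$err_euclid_mm[records$mode == m1]
      b <- records$err_euclid_mm[records$mode == m2]
      ok <- length(a) >= 2L && length(b) >= 2L
      tt <- if (ok && (stats::var(a) > 0 || stats::var(b) > 0))
        two_sample_t(a, b) else list(t = NA, dof = NA, p = NA)
      ft <- if (ok && stats::var(a) > 0 && stats::var(b) > 0)
        variance_f_test(a, b) else list(F = NA, dof1 = NA, dof2 = NA, p = NA)
      data.frame(mode_a = m1, mode_b = m2,
                 t = tt$t, t_dof = tt$dof, t_p = tt$p,
                 F = ft$F, F_dof1 = ft$dof1, F_dof2 = ft$dof2, F_p = ft$p)
    }))
  }
  list(per_mode = per_mode, pairwise = pairwise)
}

#' The ten clinical-case effective diameters (mm)
#'
#' Effective GTV diameters of the ten solid-lung-tumor cases driving the
#' clinical-like simulation (range 5.38-14.35 mm, mean 10.43 mm).
#'
#' @return numeric vector of length 10.
#' @export
table1_diameters <- function() {
  c(9.35, 12.30, 11.94, 10.07, 12.91, 14.35, 5.90, 5.38, 9.00, 13.12)
}
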