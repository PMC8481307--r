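#' Partial-least-squares correlation of demographics and neural features
#'
#' Relates a demographics block `x` to a neural-feature block `y` by
#' singular value decomposition of their cross-block correlation matrix:
#' both blocks are z-scored column-wise, `R = t(X) Y / (n - 1)` is
#' decomposed as `R = U S V'`, and each latent variable (LV) pairs a
#' demographic salience column of `U` with a neural salience column of `V`.
#' Subject scores are `X U` and `Y V`. The squared singular values sum to
#' the squared Frobenius norm of `R`.
#'
#' @param x Demographics: numeric matrix or data frame (n subjects x q
#'   variables). Categorical binary variables should be coded numerically
#'   (see [encode_demographics()]).
#' @param y Neural features: numeric matrix, data frame, or
#'   [feature_matrix()] (n subjects x p features).
#' @return A `pls_result`: list with `singular_values`,
#'   `demographic_saliences` (q x L), `neural_saliences` (p x L),
#'   `x_scores`, `y_scores` (n x L), the z-scored blocks, and labels.
#' @export
pls_fit <- function(x, y) {
  xm <- pls_block(x, "x")
  ym <- pls_block(y, "y")
  if (nrow(xm) != nrow(ym)) abort("`x` and `y` must have the same subjects.")
  n <- nrow(xm)
  if (n < 3) abort("PLS needs at least 3 subjects.")
  zx <- zscore_cols(xm, "x")
  zy <- zscore_cols(ym, "y")
  r <- crossprod(zx, zy) / (n - 1)
  sv <- svd(r)
  structure(
    list(
      singular_values = sv$d,
      demographic_saliences = sv$u,
      neural_saliences = sv$v,
      x_scores = zx %*% sv$u,
      y_scores = zy %*% sv$v,
      zx = zx,
      zy = zy,
      x_labels = colnames(xm),
      y_labels = colnames(ym),
      n = n
    ),
    class = "pls_result"
  )
}

pls_block <- function(b, name) {
  if (inherits(b, "feature_matrix")) {
    m <- b$values
    colnames(m) <- b$feature_labels
    return(m)
  }
  if (is.data.frame(b)) {
    b <- dplyr::select(b, dplyr::where(is.numeric))
    m <- as.matrix(b)
    return(m)
  }
  m <- as.matrix(b)
  if (is.null(colnames(m))) colnames(m) <- paste0(name, seq_len(ncol(m)))
  m
}

zscore_cols <- function(m, name) {
  sds <- apply(m, 2, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(m)[sds == 0 | !is.finite(sds)]
    abort(sprintf("Constant column(s) in `%s`: %s", name,
                  paste(bad, collapse = ", ")))
  }
  scale(m)
}

#' Encode a demographics table for PLS
#'
#' Keeps numeric columns and converts binary/categorical columns (factors,
#' characters, logicals) to centered binary codes; the subject id column is
#' dropped.
#'
#' @param demographics Tibble with one row per subject.
#' @param id_col Name of the subject id column (default `"subject_id"`).
#' @return Numeric matrix with one column per demographic variable.
#' @export
encode_demographics <- function(demographics, id_col = "subject_id") {
  d <- demographics[, setdiff(names(demographics), id_col), drop = FALSE]
  cols <- lapply(names(d), function(nm) {
    v <- d[[nm]]
    if (is.numeric(v)) return(v)
    f <- as.factor(v)
    if (nlevels(f) != 2) {
      abort(sprintf("Column '%s' is categorical with %d levels; only binary categoricals are supported.",
                    nm, nlevels(f)))
    }
    as.numeric(f) - 1.5 # centered binary code
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(d)
  m
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d LV(s), n = %d; singular values: %s\n",
              length(x$singular_values), x$n,
              paste(signif(head(x$singular_values, 5), 3), collapse = ", ")))
  if (!is.null(x$p_perm)) {
    cat(sprintf("  permutation p (LV1..): %s\n",
                paste(signif(head(x$p_perm, 5), 3), collapse = ", ")))
  }
  invisible(x)
}

#' Permutation test for PLS latent variables
#'
#' Re-runs the decomposition after shuffling the rows of the demographic
#' block, `n_perm` times; the p-value of LV `k` is
#' `(#{permuted S_k >= observed S_k} + 1) / (n_perm + 1)`.
#'
#' @param fit A [pls_fit()] result.
#' @param n_perm Number of permutations (large-cohort analyses typically use
#'   10,000).
#' @param seed Integer seed; fixed seed gives identical p-values.
#' @return The fit with `p_perm` (per LV) and `perm_singular_values`
#'   (n_perm x L) added.
#' @export
pls_permutation <- function(fit, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(fit, "pls_result"))
  if (n_perm < 100) abort("Use at least 100 permutations.")
  n <- fit$n
  l <- length(fit$singular_values)
  perm_d <- matrix(NA_real_, n_perm, l)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      r <- crossprod(fit$zx[idx, , drop = FALSE], fit$zy) / (n - 1)
      perm_d[b, ] <- svd(r, nu = 0, nv = 0)$d
    }
  })
  fit$p_perm <- vapply(seq_len(l), function(k) {
    (sum(perm_d[, k] >= fit$singular_values[k]) + 1) / (n_perm + 1)
  }, numeric(1))
  fit$perm_singular_values <- perm_d
  fit$n_perm <- n_perm
  fit
}

#' Bootstrap stability of PLS saliences
#'
#' Resamples subjects with replacement, re-fits the decomposition, aligns
#' each resample's LVs to the original by orthogonal Procrustes rotation of
#' the demographic saliences (resolves sign and order indeterminacy), and
#' reports: the bootstrap ratio of each neural salience (original weight /
#' bootstrap SE, capped at `ratio_cap` when the SE underflows, with a flag)
#' and 95% percentile confidence intervals for the demographic saliences
#' (which need not be symmetric around the point estimate). Resamples that
#' produce a constant column are dropped and counted.
#'
#' @param fit A [pls_fit()] result.
#' @param n_boot Number of bootstrap resamples (typically
#'   10,000).
#' @param seed Integer seed.
#' @param ratio_cap Cap for bootstrap ratios with near-zero SE.
#' @return The fit with `bootstrap_ratio` (p x L), `ratio_capped` (logical
#'   p x L), `ci95` (q x L x 2), `n_boot_used`, `n_boot_dropped` added.
#' @export
pls_bootstrap <- function(fit, n_boot = 1000, seed = 1L, ratio_cap = 1e6) {
  stopifnot(inherits(fit, "pls_result"))
  if (n_boot < 100) abort("Use at least 100 bootstrap resamples.")
  n <- fit$n
  l <- length(fit$singular_values)
  q <- ncol(fit$zx)
  p <- ncol(fit$zy)
  u0 <- fit$demographic_saliences
  u_boot <- array(NA_real_, c(n_boot, q, l))
  v_boot <- array(NA_real_, c(n_boot, p, l))
  dropped <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      xb <- fit$zx[idx, , drop = FALSE]
      yb <- fit$zy[idx, , drop = FALSE]
      sx <- apply(xb, 2, sd)
      sy <- apply(yb, 2, sd)
      if (any(sx == 0) || any(sy == 0)) {
        dropped <- dropped + 1L
        next
      }
      r <- crossprod(scale(xb), scale(yb)) / (n - 1)
      sv <- svd(r)
      # Procrustes alignment of demographic saliences to the original
      pr <- svd(crossprod(sv$u[, seq_len(l), drop = FALSE], u0))
      rot <- pr$u %*% t(pr$v)
      u_boot[b, , ] <- sv$u[, seq_len(l), drop = FALSE] %*% rot
      v_boot[b, , ] <- sv$v[, seq_len(l), drop = FALSE] %*% rot
    }
  })
  ok <- !is.na(u_boot[, 1, 1])
  se_v <- apply(v_boot[ok, , , drop = FALSE], c(2, 3), sd)
  ratio <- fit$neural_saliences / se_v
  capped <- !is.finite(ratio) | abs(ratio) > ratio_cap
  ratio[capped] <- sign(fit$neural_saliences[capped]) * ratio_cap
  ci <- array(NA_real_, c(q, l, 2),
              dimnames = list(NULL, NULL, c("lo", "hi")))
  for (j in seq_len(q)) {
    for (k in seq_len(l)) {
      ci[j, k, ] <- quantile(u_boot[ok, j, k], c(0.025, 0.975), names = FALSE)
    }
  }
  fit$bootstrap_ratio <- ratio
  fit$ratio_capped <- capped
  fit$ci95 <- ci
  fit$n_boot_used <- sum(ok)
  fit$n_boot_dropped <- dropped
  fit
}

#' @describeIn pls_fit Tidy saliences and inference. `which` selects the
#'   block: `"demographic"` (saliences + CI when bootstrapped) or
#'   `"neural"` (saliences + bootstrap ratio when bootstrapped).
#' @param x A `pls_result`.
#' @param which `"demographic"` or `"neural"`.
#' @param ... Unused.
#' @export
tidy.pls_result <- function(x, which = c("demographic", "neural"), ...) {
  which <- match.arg(which)
  l <- length(x$singular_values)
  if (which == "demographic") {
    out <- tibble(
      term = rep(x$x_labels, times = l),
      lv = rep(seq_len(l), each = length(x$x_labels)),
      salience = as.vector(x$demographic_saliences)
    )
    if (!is.null(x$ci95)) {
      out$ci_lo <- as.vector(x$ci95[, , "lo"])
      out$ci_hi <- as.vector(x$ci95[, , "hi"])
    }
  } else {
    out <- tibble(
      term = rep(x$y_labels, times = l),
      lv = rep(seq_len(l), each = length(x$y_labels)),
      salience = as.vector(x$neural_saliences)
    )
    if (!is.null(x$bootstrap_ratio)) {
      out$bootstrap_ratio <- as.vector(x$bootstrap_ratio)
      out$capped <- as.vector(x$ratio_capped)
    }
  }
  out
}

#' @describeIn pls_fit One row per LV: singular value, explained
#'   cross-block covariance fraction, permutation p when available.
#' @export
glance.pls_result <- function(x, ...) {
  d2 <- x$singular_values^2
  out <- tibble(
    lv = seq_along(x$singular_values),
    singular_value = x$singular_values,
    cov_explained = d2 / sum(d2),
    n = x$n
  )
  if (!is.null(x$p_perm)) out$p_perm <- x$p_perm
  out
}
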