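#' Joint probability mass function over 1-3 discrete variables
#'
#' A light container for an empirical (or constructed) pmf. The table is a
#' numeric vector, matrix or 3-d array of non-negative probabilities summing
#' to one. Axis roles (for example `"feature"`, `"class"`, `"ttd"`) are
#' carried along for readability and marginalisation.
#'
#' @param p Numeric vector, matrix or 3-d array; non-negative, sums to 1.
#' @param roles Optional character vector naming each axis.
#' @param tol Tolerance on the normalisation check.
#' @return An object of class `joint_pmf`.
#' @export
#' @examples
#' joint_pmf(c(0.5, 0.25, 0.25))
#' joint_pmf(matrix(c(0.25, 0, 0.25, 0.5), 2, 2), roles = c("x", "y"))
joint_pmf <- function(p, roles = NULL, tol = 1e-12) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  d <- if (is.null(dim(p))) 1L else length(dim(p))
  if (d > 3L) abort("joint_pmf supports at most 3 axes.")
  if (any(p < -tol)) abort("joint_pmf entries must be non-negative.")
  if (abs(sum(p) - 1) > max(tol, 1e-12)) {
    abort(sprintf("joint_pmf must sum to 1 (got %.15g).", sum(p)))
  }
  if (is.null(roles)) roles <- paste0("axis", seq_len(d))
  if (length(roles) != d) abort("`roles` must name every axis.")
  structure(list(p = p, d = d, roles = roles), class = "joint_pmf")
}

#' @export
print.joint_pmf <- function(x, ...) {
  dims <- if (is.null(dim(x$p))) length(x$p) else dim(x$p)
  cat("<joint_pmf> ", x$d, "-d [", paste(dims, collapse = " x "),
      "] roles: ", paste(x$roles, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Estimate a joint pmf from discrete codes
#'
#' Cross-tabulates 1-3 integer code vectors (pairwise complete rows only)
#' into an empirical [joint_pmf()].
#'
#' @param ... One to three integer/factor vectors of equal length.
#' @param roles Optional axis names; defaults to the argument names.
#' @return A `joint_pmf`.
#' @export
joint_pmf_from_codes <- function(..., roles = NULL) {
  vars <- list(...)
  if (length(vars) < 1L || length(vars) > 3L) {
    abort("Supply 1 to 3 code vectors.")
  }
  if (is.null(roles)) {
    roles <- names(vars) %||% paste0("axis", seq_along(vars))
    if (any(!nzchar(roles))) roles <- paste0("axis", seq_along(vars))
  }
  vars <- lapply(vars, function(v) if (is.factor(v)) v else factor(v))
  keep <- !Reduce(`|`, lapply(vars, is.na))
  vars <- lapply(vars, function(v) v[keep])
  n <- length(vars[[1L]])
  if (n == 0L) abort("No complete observations.")
  tab <- table(vars)
  p <- unclass(tab) / n
  dimnames(p) <- NULL
  if (length(vars) == 1L) p <- as.vector(p)
  joint_pmf(p, roles = roles)
}

#' Marginalise a joint pmf
#'
#' @param pmf A [joint_pmf()].
#' @param keep Integer indices (or role names) of the axes to keep.
#' @return A `joint_pmf` over the kept axes.
#' @export
marginalize <- function(pmf, keep) {
  stopifnot(inherits(pmf, "joint_pmf"))
  if (is.character(keep)) keep <- match(keep, pmf$roles)
  if (anyNA(keep) || any(keep < 1L | keep > pmf$d)) {
    abort("`keep` must index existing axes.")
  }
  if (pmf$d == 1L) return(pmf)
  p <- apply(pmf$p, keep, sum)
  joint_pmf(p, roles = pmf$roles[keep])
}

plogp_sum <- function(p, base) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Shannon entropy of a 1-d pmf
#'
#' \eqn{H(X) = -\sum_x p(x) \log p(x)}, with the convention
#' \eqn{0 \log 0 = 0}. Accepts a 1-d [joint_pmf()] or a bare probability
#' vector (which is validated).
#'
#' @param pmf 1-d `joint_pmf` or numeric probability vector.
#' @param base Logarithm base; 2 (bits) by default.
#' @return Entropy in `log base` units.
#' @export
#' @examples
#' entropy(rep(0.25, 4))          # 2 bits
#' entropy(c(0.5, 0.25, 0.25))    # 1.5 bits
entropy <- function(pmf, base = 2) {
  if (!inherits(pmf, "joint_pmf")) pmf <- joint_pmf(pmf)
  if (pmf$d != 1L) abort("entropy() needs a 1-d pmf; marginalize() first.")
  plogp_sum(pmf$p, base)
}

#' Mutual information of a 2-d pmf
#'
#' \eqn{I(X;Y) = \sum_{x,y} p(x,y) \log\frac{p(x,y)}{p(x)p(y)}}; cells with
#' \eqn{p(x,y) = 0} contribute nothing.
#'
#' @param joint 2-d [joint_pmf()] (or matrix of probabilities).
#' @param base Logarithm base (default 2, bits).
#' @return Mutual information in `log base` units.
#' @export
#' @examples
#' mutual_information(matrix(c(0.25, 0, 0.25, 0.5), 2, 2))  # ~0.3113 bits
mutual_information <- function(joint, base = 2) {
  if (!inherits(joint, "joint_pmf")) joint <- joint_pmf(joint)
  if (joint$d != 2L) abort("mutual_information() needs a 2-d pmf.")
  p <- joint$p
  px <- rowSums(p)
  py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / outer(px, py)[pos])) / log(base)
}

#' Normalized mutual information
#'
#' \eqn{NMI_X(X;Y) = I(X;Y) / H(X)}, bounded in `[0, 1]`. The normalising
#' axis is selected by index or role name.
#'
#' @param joint 2-d [joint_pmf()].
#' @param normalize_by Axis (1, 2, or a role name) whose entropy divides I.
#' @param base Logarithm base (NMI itself is base-invariant).
#' @return NMI in `[0, 1]`.
#' @export
normalized_mi <- function(joint, normalize_by = 1L, base = 2) {
  if (!inherits(joint, "joint_pmf")) joint <- joint_pmf(joint)
  if (joint$d != 2L) abort("normalized_mi() needs a 2-d pmf.")
  if (is.character(normalize_by)) normalize_by <- match(normalize_by, joint$roles)
  h <- entropy(marginalize(joint, normalize_by), base = base)
  if (!is.finite(h) || h <= 0) {
    abort("Normalising variable is degenerate (zero entropy).",
          class = "ctgtime_degenerate_feature")
  }
  mutual_information(joint, base = base) / h
}

#' Conditional mutual information of a 3-d pmf
#'
#' \eqn{I(X;Y\mid Z) = \sum_{x,y,z} p(x,y,z)
#'   \log\frac{p(z)\,p(x,y,z)}{p(x,z)\,p(y,z)}}. Axes are taken in order
#' (X, Y, Z).
#'
#' @param joint3 3-d [joint_pmf()] (or 3-d array of probabilities).
#' @param base Logarithm base (default 2).
#' @return Conditional mutual information in `log base` units.
#' @export
conditional_mi <- function(joint3, base = 2) {
  if (!inherits(joint3, "joint_pmf")) joint3 <- joint_pmf(joint3)
  if (joint3$d != 3L) abort("conditional_mi() needs a 3-d pmf.")
  p <- joint3$p
  pz <- apply(p, 3, sum)
  pxz <- apply(p, c(1, 3), sum)
  pyz <- apply(p, c(2, 3), sum)
  acc <- 0
  dims <- dim(p)
  for (k in seq_len(dims[3])) {
    pk <- p[, , k, drop = FALSE]
    dim(pk) <- dims[1:2]
    pos <- pk > 0
    if (!any(pos)) next
    denom <- outer(pxz[, k], pyz[, k])
    acc <- acc + sum(pk[pos] * log(pz[k] * pk[pos] / denom[pos]))
  }
  acc / log(base)
}

#' Conditional normalized mutual information
#'
#' \eqn{NMI_X(X;Y\mid Z) = I(X;Y\mid Z)/H(X)}, used to quantify the
#' class-feature association given time to delivery.
#'
#' @inheritParams conditional_mi
#' @param normalize_by Axis (1-3 or role name) whose marginal entropy
#'   divides the conditional mutual information.
#' @return Conditional NMI in `[0, 1]`.
#' @export
conditional_nmi <- function(joint3, normalize_by = 1L, base = 2) {
  if (!inherits(joint3, "joint_pmf")) joint3 <- joint_pmf(joint3)
  if (joint3$d != 3L) abort("conditional_nmi() needs a 3-d pmf.")
  if (is.character(normalize_by)) normalize_by <- match(normalize_by, joint3$roles)
  h <- entropy(marginalize(joint3, normalize_by), base = base)
  if (!is.finite(h) || h <= 0) {
    abort("Normalising variable is degenerate (zero entropy).",
          class = "ctgtime_degenerate_feature")
  }
  conditional_mi(joint3, base = base) / h
}
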