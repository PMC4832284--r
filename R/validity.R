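#' Negative log likelihood from a residual sum of squares
#'
#' For a Gaussian GLM with n observations and residual sum of squares RSS,
#' the (complexity-free) negative log likelihood is `NLL = n * log(RSS / n)`.
#' Smaller NLL indicates a better separation of the experimental conditions,
#' i.e. higher predictive validity. Model complexity is disregarded, so NLL
#' values are only comparable across methods at identical n and design.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n Number of observations (>= 1).
#' @return `n * log(rss / n)`; `-Inf` with a warning when `rss` is 0
#'   (degenerate, perfect fit).
#' @examples
#' nll_from_rss(60, 600)  # 600 * log(0.1)
#' @export
nll_from_rss <- function(rss, n) {
  if (rss < 0) stop("'rss' must be >= 0", call. = FALSE)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (rss == 0) {
    warning("RSS is zero: NLL is -Inf (degenerate perfect fit)",
            call. = FALSE)
    return(-Inf)
  }
  n * log(rss / n)
}

#' Log Bayes factor between two methods
#'
#' The LBF of a method against a reference is the difference in NLL computed
#' on the same observations with the same design complexity. Negative values
#' favour the method over the reference. An absolute LBF above 3 is commonly
#' treated as decisive, by analogy with a classical p value: the posterior
#' probability of the losing model is at most 1/exp(3) <= 0.05.
#'
#' @param nll_method,nll_reference NLL values from [nll_from_rss()] computed
#'   on identical observations.
#' @return A list with `lbf` (the difference) and `decisive`
#'   (`abs(lbf) > 3`).
#' @export
lbf <- function(nll_method, nll_reference) {
  d <- nll_method - nll_reference
  list(lbf = d, decisive = is.finite(d) && abs(d) > 3)
}

.contrast_result <- function(fit, term, design) {
  rss <- sum(stats::residuals(fit)^2)
  n <- length(stats::residuals(fit))
  if (stats::df.residual(fit) < 1 || rss <= .Machine$double.eps * n)
    stop("degenerate input: condition effect has no residual variance, ",
         "t statistic undefined", call. = FALSE)
  tt <- summary(fit)$coefficients[term, "t value"]
  structure(list(rss = rss, n = n, nll = nll_from_rss(rss, n),
                 t_stat = unname(tt), dof = stats::df.residual(fit),
                 design = design),
            class = "sf_contrast")
}

#' @export
print.sf_contrast <- function(x, ...) {
  cat(sprintf("<sf_contrast> %s design: t(%d) = %.3f, RSS = %.4g, NLL = %.2f (n = %d)\n",
              x$design, x$dof, x$t_stat, x$rss, x$nll, x$n))
  invisible(x)
}

#' Within-subject (paired) condition contrast
#'
#' Fits the GLM `value ~ intercept + condition + subject` by least squares on
#' the stacked per-subject arousal estimates of the two conditions. The t
#' statistic for the condition effect is identical to the closed-form paired
#' t test; the residual sum of squares is converted to an NLL with
#' [nll_from_rss()]. Because subject effects are in the design, adding any
#' per-subject constant leaves both t and NLL differences unchanged.
#'
#' @param values_a,values_b Arousal estimates (e.g. SF per minute) for
#'   conditions A and B, same subjects in the same order, length >= 2.
#' @return An `sf_contrast` (see [nll_from_rss()]); `t_stat` is positive when
#'   condition B exceeds condition A.
#' @export
paired_contrast <- function(values_a, values_b) {
  n <- length(values_a)
  if (n < 2L || length(values_b) != n)
    stop("paired contrast needs two equal-length vectors (>= 2 subjects)",
         call. = FALSE)
  y <- c(values_a, values_b)
  cond <- factor(rep(c("a", "b"), each = n))
  subj <- factor(rep(seq_len(n), 2L))
  fit <- stats::lm(y ~ cond + subj)
  .contrast_result(fit, "condb", "paired")
}

#' Between-subject (independent) condition contrast
#'
#' Fits the GLM `value ~ intercept + group` on per-participant values
#' (typically treatment-minus-rest differences). The t statistic equals the
#' closed-form independent-samples t test with pooled variance.
#'
#' @param group_a,group_b Per-participant values for the two groups, each of
#'   length >= 2.
#' @return An `sf_contrast`; `t_stat` is positive when group B exceeds
#'   group A.
#' @export
independent_contrast <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("independent contrast needs >= 2 values per group", call. = FALSE)
  y <- c(group_a, group_b)
  grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  fit <- stats::lm(y ~ grp)
  .contrast_result(fit, "grpb", "independent")
}

#' Score several estimation methods on a long-format epoch table
#'
#' Computes, per method, the condition contrast and its NLL, and the log
#' Bayes factor against a reference method. The table must hold one row per
#' scored epoch with columns `subject`, `condition` (exactly two levels),
#' `method` and `value`; for the independent design an additional `group`
#' column assigns each subject to one of two groups, and the per-subject
#' treatment-minus-rest difference (second minus first condition level) is
#' contrasted between groups. Subjects missing an epoch are dropped from the
#' affected method. NLL comparisons require identical n across methods;
#' mismatched n is an error.
#'
#' @param epochs Data frame as described above.
#' @param contrast `"paired"` or `"independent"`.
#' @param reference Method name used as LBF reference (default: first method
#'   in the table).
#' @return Data frame with one row per method: `method`, `n`, `t_stat`,
#'   `dof`, `rss`, `nll`, `lbf`, `decisive`.
#' @export
score_methods <- function(epochs, contrast = c("paired", "independent"),
                          reference = NULL) {
  contrast <- match.arg(contrast)
  req <- c("subject", "condition", "method", "value",
           if (contrast == "independent") "group")
  miss <- setdiff(req, names(epochs))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  cl <- sort(unique(as.character(epochs$condition)))
  if (length(cl) != 2L)
    stop("'condition' must have exactly two levels", call. = FALSE)
  methods <- unique(as.character(epochs$method))
  if (is.null(reference)) reference <- methods[1L]
  if (!reference %in% methods)
    stop("reference method not present in table", call. = FALSE)
  one <- function(m) {
    d <- epochs[epochs$method == m, , drop = FALSE]
    wide <- merge(d[d$condition == cl[1L], c("subject", "value",
                                             if (contrast == "independent") "group")],
                  d[d$condition == cl[2L], c("subject", "value")],
                  by = "subject", suffixes = c("_a", "_b"))
    if (contrast == "paired") {
      paired_contrast(wide$value_a, wide$value_b)
    } else {
      diffs <- wide$value_b - wide$value_a
      gl <- sort(unique(as.character(wide$group)))
      if (length(gl) != 2L)
        stop("'group' must have exactly two levels", call. = FALSE)
      independent_contrast(diffs[wide$group == gl[1L]],
                           diffs[wide$group == gl[2L]])
    }
  }
  res <- lapply(methods, one)
  names(res) <- methods
  ns <- vapply(res, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("methods were scored on different numbers of observations; ",
         "NLL values are not comparable", call. = FALSE)
  ref_nll <- res[[reference]]$nll
  out <- do.call(rbind, lapply(methods, function(m) {
    r <- res[[m]]
    b <- lbf(r$nll, ref_nll)
    data.frame(method = m, n = r$n, t_stat = r$t_stat, dof = r$dof,
               rss = r$rss, nll = r$nll, lbf = b$lbf, decisive = b$decisive)
  }))
  rownames(out) <- NULL
  out
}
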