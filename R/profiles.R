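#' Build a rater's confusion matrix
#'
#' Tallies diagnoses against true labels over an evaluation set. Rows index
#' the true class, columns the diagnosed class, so entry `(l, d)` counts
#' samples of true class `l` that the rater called `d`.
#'
#' @param truth True class labels (names or indices), length N >= 1.
#' @param diagnoses The rater's diagnoses, same length.
#' @param space A [label_space()].
#' @return A `confusion_matrix`: integer C x C matrix with class-name
#'   dimnames and the label space attached.
#' @examples
#' sp <- label_space(c("a", "b"))
#' build_confusion_matrix(c(1, 1, 1, 2, 2), c(1, 2, 1, 2, 2), sp)
#' @export
build_confusion_matrix <- function(truth, diagnoses, space) {
  stopifnot(inherits(space, "label_space"))
  if (length(truth) == 0L) stop("empty evaluation set: no samples to tally")
  if (length(truth) != length(diagnoses)) {
    stop("truth (", length(truth), ") and diagnoses (", length(diagnoses),
         ") differ in length")
  }
  ti <- as_label_index(truth, space)
  di <- as_label_index(diagnoses, space)
  counts <- matrix(0L, space$C, space$C,
                   dimnames = list(true = space$names, diagnosed = space$names))
  for (n in seq_along(ti)) {
    counts[ti[n], di[n]] <- counts[ti[n], di[n]] + 1L
  }
  structure(counts, class = c("confusion_matrix", "matrix"),
            label_space = space)
}

#' Column-normalize a confusion matrix into P(true | diagnosed)
#'
#' Each column (one diagnosed class) is normalized by its total, giving the
#' distribution over true classes conditional on the rater having produced
#' that diagnosis. A diagnosis the rater never produced on the evaluation set
#' leaves a zero column; `smoothing` controls what happens then:
#' `"uniform_fallback"` (default) replaces zero columns with the uniform
#' distribution `1/C` and normalizes the rest exactly; `"laplace"` adds a
#' pseudocount `eps` to every cell before normalizing; `"none"` refuses on a
#' zero column.
#'
#' @param cm A `confusion_matrix` from [build_confusion_matrix()].
#' @param smoothing One of `"uniform_fallback"`, `"laplace"`, `"none"`.
#' @param eps Laplace pseudocount (default 0.5); only used for `"laplace"`.
#' @return A `cond_prob_matrix`: C x C column-stochastic matrix, with a
#'   `smoothing` attribute recording the mode, pseudocount, and which
#'   diagnosis columns (if any) fell back to uniform.
#' @export
conditional_from_confusion <- function(cm,
                                       smoothing = c("uniform_fallback",
                                                     "laplace", "none"),
                                       eps = 0.5) {
  stopifnot(inherits(cm, "confusion_matrix"))
  smoothing <- match.arg(smoothing)
  space <- attr(cm, "label_space")
  counts <- unclass(cm)
  csums <- colSums(counts)
  fallback_cols <- character(0)

  if (smoothing == "none") {
    if (any(csums == 0)) {
      never <- space$names[csums == 0]
      stop("diagnosis class never produced by the rater: ",
           paste(never, collapse = ", "),
           "; use laplace or uniform_fallback smoothing")
    }
    probs <- sweep(counts, 2L, csums, "/")
  } else if (smoothing == "laplace") {
    sm <- counts + eps
    probs <- sweep(sm, 2L, colSums(sm), "/")
  } else {
    probs <- matrix(1 / space$C, space$C, space$C)
    nz <- csums > 0
    probs[, nz] <- sweep(counts[, nz, drop = FALSE], 2L, csums[nz], "/")
    fallback_cols <- space$names[!nz]
  }

  dimnames(probs) <- list(true = space$names, diagnosed = space$names)
  structure(probs, class = c("cond_prob_matrix", "matrix"),
            label_space = space,
            smoothing = list(mode = smoothing,
                             eps = if (smoothing == "laplace") eps else NA_real_,
                             fallback_columns = fallback_cols))
}

#' Expand a single diagnosis into a probability over true classes
#'
#' Reads off the column of the conditional matrix for the diagnosed class:
#' the rater's class-specific tendency turned into a probability vector for
#' one test sample.
#'
#' @param diagnosis Class index (1-based) or class name.
#' @param cond A `cond_prob_matrix`.
#' @return Numeric length-C probability vector (sums to 1).
#' @export
expand_response <- function(diagnosis, cond) {
  stopifnot(inherits(cond, "cond_prob_matrix"))
  space <- attr(cond, "label_space")
  d <- as_label_index(diagnosis, space)
  if (length(d) != 1L) stop("expand_response takes a single diagnosis")
  as.numeric(unclass(cond)[, d])
}

#' One-hot delta response for a diagnosis
#'
#' @param diagnosis Class index or name.
#' @param space A `label_space`.
#' @return Length-C vector with a single 1 at the diagnosed class.
#' @export
delta_response <- function(diagnosis, space) {
  d <- as_label_index(diagnosis, space)
  if (length(d) != 1L) stop("delta_response takes a single diagnosis")
  v <- numeric(space$C)
  v[d] <- 1
  v
}

#' Overall accuracy of a confusion matrix
#'
#' Trace over total: the fraction of evaluation samples the rater diagnosed
#' correctly.
#'
#' @param cm A `confusion_matrix`.
#' @return Fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix: accuracy undefined")
  sum(diag(unclass(cm))) / total
}

#' Build a full rater profile from labeled evaluation data
#'
#' Convenience wrapper: confusion matrix, conditional matrix, overall
#' accuracy and the per-sample delta / conditional feature matrices used by
#' the cooperation schemes.
#'
#' @inheritParams build_confusion_matrix
#' @inheritParams conditional_from_confusion
#' @return A list of class `rater_profile` with elements `confusion`,
#'   `conditional`, `accuracy`, `n_eval`, `space`.
#' @export
rater_profile <- function(truth, diagnoses, space,
                          smoothing = "uniform_fallback", eps = 0.5) {
  cm <- build_confusion_matrix(truth, diagnoses, space)
  cond <- conditional_from_confusion(cm, smoothing, eps)
  structure(list(confusion = cm,
                 conditional = cond,
                 accuracy = overall_accuracy(cm),
                 n_eval = sum(cm),
                 space = space),
            class = "rater_profile")
}

#' @export
print.rater_profile <- function(x, ...) {
  cat("rater profile over", x$space$C, "classes (",
      x$n_eval, "evaluation samples )\n")
  cat(sprintf("overall accuracy: %.4f\n", x$accuracy))
  sm <- attr(x$conditional, "smoothing")
  cat("smoothing:", sm$mode)
  if (length(sm$fallback_columns)) {
    cat(" (uniform fallback for:",
        paste(sm$fallback_columns, collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

# one-hot feature matrix (N x C) for a diagnosis sequence
delta_matrix <- function(diagnoses, space) {
  d <- as_label_index(diagnoses, space)
  m <- matrix(0, length(d), space$C,
              dimnames = list(NULL, space$names))
  m[cbind(seq_along(d), d)] <- 1
  m
}

# conditional feature matrix (N x C): row n = cond column of diagnosis n
cond_matrix_for <- function(diagnoses, cond) {
  space <- attr(cond, "label_space")
  d <- as_label_index(diagnoses, space)
  m <- t(unclass(cond))[d, , drop = FALSE]
  dimnames(m) <- list(NULL, space$names)
  m
}
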