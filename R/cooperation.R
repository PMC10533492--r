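#' Average machine probability vectors for one sample
#'
#' Elementwise mean of the M models' softmax outputs; reduces a panel slice
#' to a single machine probability vector.
#'
#' @param panel_slice M x C matrix (one row per model) or a single vector.
#' @return Length-C probability vector.
#' @export
average_machines <- function(panel_slice) {
  if (is.vector(panel_slice)) panel_slice <- matrix(panel_slice, nrow = 1L)
  if (nrow(panel_slice) == 0L) stop("empty machine panel: nothing to average")
  colMeans(panel_slice)
}

# N x C machine average over the whole panel (N x C x M)
panel_mean <- function(panel) {
  stopifnot(length(dim(panel)) == 3L)
  apply(panel, c(1L, 2L), mean)
}

#' Alpha-weighted vote between machine sum and a human diagnosis
#'
#' Sums the M machine softmax vectors and adds `alpha` times the human's
#' one-hot delta response; the decision is the argmax. `alpha = 0` ignores
#' the human; `alpha = 4` (with 4 models, each probability below 1) always
#' follows the human.
#'
#' @param machine_vectors M x C matrix of softmax vectors.
#' @param human_class Diagnosed class index or name.
#' @param alpha Human weight in `[0, 4]`.
#' @param space A `label_space` (needed to interpret `human_class`).
#' @return List with `score` (length-C) and `class` (index, lowest-index
#'   tie-break).
#' @export
alpha_vote <- function(machine_vectors, human_class, alpha, space) {
  if (alpha < 0 || alpha > 4) stop("alpha must lie in [0, 4], got ", alpha)
  if (is.vector(machine_vectors)) {
    machine_vectors <- matrix(machine_vectors, nrow = 1L)
  }
  if (ncol(machine_vectors) != space$C) {
    stop("machine vectors have ", ncol(machine_vectors),
         " columns but the label space has ", space$C, " classes")
  }
  score <- colSums(machine_vectors) + alpha * delta_response(human_class, space)
  list(score = as.numeric(score), class = classify(score))
}

#' Equal-weight average of machine and human conditional probabilities
#'
#' `0.5 * pm + 0.5 * ph`: the unoptimized scheme that uses the rater's
#' class-specific tendency but not their overall accuracy.
#'
#' @param pm Machine probability vector (length C).
#' @param ph Human conditional probability vector (length C).
#' @return Length-C score vector (sums to 1 for valid inputs).
#' @export
combine_cavg <- function(pm, ph) {
  check_same_length(pm, ph)
  0.5 * pm + 0.5 * ph
}

#' Optimally weighted average of machine probability and delta response
#'
#' `(1 - w) * pm + w * delta`: uses the rater's overall accuracy (through
#' the fitted `w`) but not their class-specific tendency.
#'
#' @param pm Machine probability vector.
#' @param human_class Diagnosed class (index or name).
#' @param w Human weight in `[0, 1]`.
#' @param space A `label_space`.
#' @return Length-C score vector.
#' @export
combine_popt <- function(pm, human_class, w, space) {
  check_unit_weight(w)
  d <- delta_response(human_class, space)
  check_same_length(pm, d)
  (1 - w) * pm + w * d
}

#' Optimally weighted average of machine and conditional probabilities
#'
#' `(1 - w) * pm + w * ph`: uses both the rater's overall accuracy and their
#' class-specific tendency. At `w = 0.5` it coincides with [combine_cavg()].
#'
#' @param pm Machine probability vector.
#' @param ph Human conditional probability vector.
#' @param w Human weight in `[0, 1]`.
#' @return Length-C score vector.
#' @export
combine_pcopt <- function(pm, ph, w) {
  check_unit_weight(w)
  check_same_length(pm, ph)
  (1 - w) * pm + w * ph
}

#' Per-classifier, per-class weighted combination
#'
#' Stacks the M machine vectors and the human conditional vector for one
#' sample and applies a full (M+1) x C weight matrix:
#' `score[c] = sum_k stack[k, c] * W[k, c]`.
#'
#' @param stack (M+1) x C matrix; rows are machine models then the human.
#' @param W (M+1) x C nonnegative weight matrix.
#' @return Length-C score vector (not normalized).
#' @export
combine_matrix <- function(stack, W) {
  if (!all(dim(stack) == dim(W))) {
    stop("stack is ", nrow(stack), "x", ncol(stack), " but W is ",
         nrow(W), "x", ncol(W))
  }
  colSums(stack * W)
}

#' Decide a class from a score vector
#'
#' Argmax with a deterministic tie-break toward the lowest class index.
#'
#' @param score Length-C finite score vector.
#' @return Class index in `1:C`.
#' @export
classify <- function(score) {
  score <- as.numeric(score)
  if (length(score) == 0L || all(is.na(score))) {
    stop("cannot classify an empty or all-NA score vector")
  }
  if (any(!is.finite(score))) stop("non-finite score entries")
  which.max(score) # which.max returns the first (lowest-index) maximum
}

check_unit_weight <- function(w) {
  if (length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    stop("weight w must be a single value in [0, 1], got ",
         paste(w, collapse = ", "))
  }
  invisible(w)
}

check_same_length <- function(a, b) {
  if (length(a) != length(b)) {
    stop("probability vectors differ in length: ",
         length(a), " vs ", length(b))
  }
  invisible(NULL)
}
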