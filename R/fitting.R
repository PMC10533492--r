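#' Cross-entropy between score rows and one-hot labels
#'
#' Each score row is renormalized to sum to 1 (a no-op for convex
#' combinations of probability vectors), entries are clipped to
#' `[clip_eps, 1]` so the logarithm is defined, and the mean negative
#' log-probability of the true class is returned.
#'
#' @param scores N x C matrix of nonnegative scores.
#' @param labels N x C one-hot matrix, or an integer vector of true class
#'   indices (converted internally).
#' @param clip_eps Clip floor in `(0, 1e-3]`; default 1e-9.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(scores, labels, clip_eps = 1e-9) {
  if (clip_eps <= 0 || clip_eps > 1e-3) {
    stop("clip_eps must lie in (0, 1e-3], got ", clip_eps)
  }
  scores <- as.matrix(scores)
  truth <- labels_to_index(labels, ncol(scores))
  if (length(truth) != nrow(scores)) {
    stop("scores have ", nrow(scores), " rows but labels describe ",
         length(truth), " samples")
  }
  rs <- rowSums(scores)
  if (any(rs <= 0)) {
    stop("score row(s) ", paste(which(rs <= 0), collapse = ", "),
         " sum to zero: cannot renormalize")
  }
  p <- scores / rs
  p_true <- pmin(pmax(p[cbind(seq_along(truth), truth)], clip_eps), 1)
  -mean(log(p_true))
}

#' One-hot encode class indices
#'
#' @param truth Integer class indices in `1:C` (or labels with a space).
#' @param space A `label_space`, or an integer giving C.
#' @return N x C one-hot matrix.
#' @export
one_hot <- function(truth, space) {
  C <- if (inherits(space, "label_space")) space$C else as.integer(space)
  idx <- if (inherits(space, "label_space")) as_label_index(truth, space)
         else as.integer(truth)
  m <- matrix(0, length(idx), C)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# accept one-hot matrix or index vector; return index vector
labels_to_index <- function(labels, C) {
  if (is.matrix(labels)) {
    if (ncol(labels) != C) {
      stop("label matrix has ", ncol(labels), " columns, expected ", C)
    }
    return(max.col(labels, ties.method = "first"))
  }
  as.integer(labels)
}

#' Fit the scalar human weight by cross-entropy minimization
#'
#' Finds `w* in [0, 1]` minimizing the cross-entropy of
#' `(1 - w) * pm + w * feature` against the true labels of the evaluation
#' set, where `feature` is the delta-response matrix (PoptMH) or the
#' conditional-probability matrix (PCoptMH). A dense grid (step 0.01)
#' brackets the optimum and [stats::optimize()] refines it; the procedure is
#' deterministic.
#'
#' @param pm_eval N x C machine (averaged) probability matrix.
#' @param human_feature N x C matrix: one-hot rows (PoptMH) or conditional
#'   rows (PCoptMH).
#' @param labels One-hot matrix or index vector of true classes.
#' @param scheme `"PoptMH"` or `"PCoptMH"` (recorded in the result only).
#' @param clip_eps Passed to [cross_entropy()].
#' @return A `fit_result` list: `w` (the optimum), `loss`, `scheme`,
#'   `trace` (grid losses, non-increasing best-so-far), `converged`,
#'   `n_eval`, `warnings`.
#' @export
fit_scalar_weight <- function(pm_eval, human_feature, labels,
                              scheme = c("PoptMH", "PCoptMH"),
                              clip_eps = 1e-9) {
  scheme <- match.arg(scheme)
  pm_eval <- as.matrix(pm_eval)
  human_feature <- as.matrix(human_feature)
  stopifnot(all(dim(pm_eval) == dim(human_feature)))
  truth <- labels_to_index(labels, ncol(pm_eval))
  warns <- character(0)
  if (length(unique(truth)) < 2L) {
    warns <- c(warns, "degenerate evaluation set: a single true class present")
  }

  loss_at <- function(w) {
    cross_entropy((1 - w) * pm_eval + w * human_feature, truth, clip_eps)
  }

  grid <- seq(0, 1, by = 0.01)
  grid_loss <- vapply(grid, loss_at, numeric(1))
  k <- which.min(grid_loss)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  if (lo == hi) {
    w_star <- lo
    loss_star <- grid_loss[k]
  } else {
    opt <- stats::optimize(loss_at, c(lo, hi), tol = 1e-9)
    if (opt$objective <= grid_loss[k]) {
      w_star <- opt$minimum
      loss_star <- opt$objective
    } else {
      w_star <- grid[k]
      loss_star <- grid_loss[k]
    }
  }

  structure(list(w = w_star, loss = loss_star, scheme = scheme,
                 trace = list(grid = grid, grid_loss = grid_loss,
                              best = cummin(grid_loss)),
                 converged = TRUE, n_eval = nrow(pm_eval),
                 warnings = warns),
            class = "fit_result")
}

#' Fit the full per-classifier, per-class weight matrix
#'
#' Minimizes the cross-entropy of the weighted combination
#' `score[n, c] = sum_k stack_k[n, c] * W[k, c]` over nonnegative
#' (M+1) x C weight matrices by projected gradient descent with backtracking
#' line search: uniform initialization at `1/(M+1)`, projection onto the
#' nonnegative orthant, iteration cap, and a tolerance on the loss change.
#' The trace of accepted losses is non-increasing by construction.
#'
#' @param panel_eval N x C x M machine panel for the evaluation set.
#' @param ph_eval N x C human conditional-probability matrix.
#' @param labels One-hot matrix or index vector of true classes.
#' @param max_iter Iteration cap (default 5000).
#' @param tol Stop when the loss decreases by less than this (default 1e-10).
#' @param clip_eps Passed to [cross_entropy()].
#' @param row_constant If `TRUE`, constrain every row of `W` to a single
#'   scalar (one weight per classifier); the fit then spans the same model
#'   family as the scalar convex combination, up to overall scale.
#' @return A `fit_result` list: `W` ((M+1) x C), `loss`, `trace`
#'   (loss per accepted iteration), `converged`, `n_eval`.
#' @export
fit_weight_matrix <- function(panel_eval, ph_eval, labels,
                              max_iter = 5000L, tol = 1e-10,
                              clip_eps = 1e-9, row_constant = FALSE) {
  stopifnot(length(dim(panel_eval)) == 3L)
  N <- dim(panel_eval)[1L]
  C <- dim(panel_eval)[2L]
  M <- dim(panel_eval)[3L]
  ph_eval <- as.matrix(ph_eval)
  stopifnot(nrow(ph_eval) == N, ncol(ph_eval) == C)
  truth <- labels_to_index(labels, C)

  # stack of K = M + 1 classifier matrices, each N x C
  K <- M + 1L
  stacks <- vector("list", K)
  for (m in seq_len(M)) stacks[[m]] <- matrix(panel_eval[, , m], N, C)
  stacks[[K]] <- ph_eval

  score_of <- function(W) {
    S <- matrix(0, N, C)
    for (k in seq_len(K)) {
      S <- S + stacks[[k]] * matrix(W[k, ], N, C, byrow = TRUE)
    }
    S
  }
  loss_of <- function(W) cross_entropy(score_of(W), truth, clip_eps)
  grad_of <- function(W) {
    S <- score_of(W)
    r <- rowSums(S)
    s_true <- pmax(S[cbind(seq_len(N), truth)], clip_eps)
    # d loss / d S[n, c] for loss = -(1/N) sum log( S[n, y_n] / r_n )
    dS <- matrix(1 / r, N, C) # from -(-1/r_n) per column
    dS[cbind(seq_len(N), truth)] <- dS[cbind(seq_len(N), truth)] - 1 / s_true
    dS <- dS / N
    G <- matrix(0, K, C)
    for (k in seq_len(K)) G[k, ] <- colSums(stacks[[k]] * dS)
    G
  }

  project <- function(W) {
    if (row_constant) W <- matrix(rowMeans(W), K, C)
    pmax(W, 0)
  }

  W <- matrix(1 / K, K, C)
  loss <- loss_of(W)
  trace <- loss
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    G <- grad_of(W)
    accepted <- FALSE
    for (bt in 1:30) {
      W_new <- project(W - step * G)
      loss_new <- loss_of(W_new)
      if (loss_new <= loss) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      converged <- TRUE # no descent direction at machine precision
      break
    }
    improved <- loss - loss_new
    W <- W_new
    loss <- loss_new
    trace <- c(trace, loss)
    step <- step * 1.2 # gentle growth so the line search stays short
    if (improved < tol) {
      converged <- TRUE
      break
    }
  }

  structure(list(W = W, loss = loss, scheme = "matrix",
                 trace = trace, converged = converged,
                 iterations = length(trace) - 1L, n_eval = N),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("cooperation weight fit (", x$scheme, ")\n", sep = "")
  if (!is.null(x$w)) cat(sprintf("w* = %.6f\n", x$w))
  if (!is.null(x$W)) {
    cat("W* (", nrow(x$W), "x", ncol(x$W), "), row sums: ",
        paste(sprintf("%.3f", rowSums(x$W)), collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("final loss = %.8f over %d evaluation samples\n",
              x$loss, x$n_eval))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
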