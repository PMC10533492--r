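#' Define an ordered label space
#'
#' A label space fixes the class identifiers and their order for a whole
#' analysis run; every confusion matrix, probability vector and panel built
#' against it uses the same index order.
#'
#' @param names Character vector of unique class identifiers (at least 2).
#' @return An object of class `label_space` with elements `names` and `C`.
#' @examples
#' sp <- label_space(c("A", "B", "C"))
#' sp$C
#' @export
label_space <- function(names) {
  names <- as.character(names)
  if (length(names) < 2L) {
    stop("a label space needs at least 2 classes, got ", length(names))
  }
  if (anyDuplicated(names)) {
    stop("duplicate class names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  structure(list(names = names, C = length(names)), class = "label_space")
}

#' @export
print.label_space <- function(x, ...) {
  cat("label space with", x$C, "classes:",
      paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Default otoendoscopy label space
#'
#' The six tympanic-membrane classes used throughout the examples:
#' tympanic perforation (Tp), attic retraction/atelectasis (Ar),
#' myringitis/otitis externa (Myri), otitis media with effusion (Ome),
#' tumors (Tumor), and normal (No).
#'
#' @return A `label_space` of size 6.
#' @export
otoscopy_labels <- function() {
  label_space(c("Tp", "Ar", "Myri", "Ome", "Tumor", "No"))
}

#' Coerce labels to 1-based class indices
#'
#' Accepts class names, a factor, or indices already in `1:C`; anything
#' outside the space is an error naming the offending label.
#'
#' @param labels Character, factor, or integer labels.
#' @param space A `label_space`.
#' @return Integer vector of indices in `1:space$C`.
#' @export
as_label_index <- function(labels, space) {
  stopifnot(inherits(space, "label_space"))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    idx <- match(labels, space$names)
    if (anyNA(idx)) {
      bad <- unique(labels[is.na(idx)])
      stop("labels not in label space: ", paste(bad, collapse = ", "))
    }
    return(as.integer(idx))
  }
  idx <- as.integer(labels)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > space$C)) {
    bad <- unique(labels[is.na(idx) | idx < 1L | idx > space$C])
    stop("label indices outside 1..", space$C, ": ",
         paste(bad, collapse = ", "))
  }
  idx
}

# run `code` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
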