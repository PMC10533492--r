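#' Write a ratings table
#'
#' Comma-delimited with header `sample_id,true_label,rater_id,diagnosis`,
#' one row per rater per sample; labels are written as class names.
#'
#' @param path Output file.
#' @param truth Integer truth labels (length N).
#' @param raters Named list of diagnosis vectors (each length N).
#' @param space A `label_space`.
#' @param sample_ids Optional ids (default `s0001...`).
#' @return The path, invisibly.
#' @export
write_ratings <- function(path, truth, raters, space, sample_ids = NULL) {
  N <- length(truth)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(N))
  ti <- as_label_index(truth, space)
  rows <- lapply(names(raters), function(r) {
    di <- as_label_index(raters[[r]], space)
    if (length(di) != N) stop("rater '", r, "' has ", length(di),
                              " diagnoses for ", N, " samples")
    data.frame(sample_id = sample_ids,
               true_label = space$names[ti],
               rater_id = r,
               diagnosis = space$names[di])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a ratings table
#'
#' Validates the header, that every label belongs to the space, and that
#' the true label of each sample is consistent across raters. Raters that
#' cover only part of the samples are flagged as partial.
#'
#' @param path Ratings file written by [write_ratings()] (or compatible).
#' @param space A `label_space`.
#' @return List with `truth` (named integer vector, ordered by sample_id),
#'   `raters` (named list of integer diagnosis vectors aligned to `truth`,
#'   NA where a rater skipped a sample), `partial` (names of raters with
#'   incomplete coverage), `sample_ids`.
#' @export
read_ratings <- function(path, space) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "true_label", "rater_id", "diagnosis")
  if (!all(need %in% names(df))) {
    stop("ratings file must have columns ", paste(need, collapse = ", "),
         "; found ", paste(names(df), collapse = ", "))
  }
  df$true_idx <- as_label_index(df$true_label, space)
  df$diag_idx <- as_label_index(df$diagnosis, space)
  # truth consistency per sample_id
  tr <- tapply(df$true_idx, df$sample_id, unique, simplify = FALSE)
  bad <- names(tr)[vapply(tr, length, integer(1)) > 1L]
  if (length(bad)) {
    vals <- paste(space$names[tr[[bad[1]]]], collapse = " vs ")
    stop("conflicting true_label for sample ", bad[1], ": ", vals)
  }
  ids <- sort(unique(df$sample_id))
  truth <- vapply(tr[ids], `[[`, integer(1), 1L)
  raters <- list()
  partial <- character(0)
  for (r in sort(unique(df$rater_id))) {
    sub <- df[df$rater_id == r, ]
    d <- rep(NA_integer_, length(ids))
    names(d) <- ids
    d[match(sub$sample_id, ids)] <- sub$diag_idx
    if (anyNA(d)) partial <- c(partial, r)
    raters[[r]] <- d
  }
  list(truth = truth, raters = raters, partial = partial, sample_ids = ids)
}

#' Write a machine probability panel
#'
#' Comma-delimited with header `sample_id,model_id,prob_<class>...` in label
#' space order; probabilities echoed at 12 significant digits.
#'
#' @param path Output file.
#' @param panel N x C x M array.
#' @param space A `label_space`.
#' @param sample_ids Optional ids (default `s0001...`).
#' @return The path, invisibly.
#' @export
write_panel <- function(path, panel, space, sample_ids = NULL) {
  stopifnot(length(dim(panel)) == 3L, dim(panel)[2L] == space$C)
  N <- dim(panel)[1L]
  M <- dim(panel)[3L]
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(N))
  model_ids <- dimnames(panel)[[3L]]
  if (is.null(model_ids)) model_ids <- paste0("M", seq_len(M))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", "model_id",
                     paste0("prob_", space$names)), collapse = ","), con)
  for (m in seq_len(M)) {
    probs <- apply(panel[, , m, drop = FALSE], 1L, function(v) {
      paste(formatC(v, digits = 12, format = "g"), collapse = ",")
    })
    writeLines(paste(sample_ids, model_ids[m], probs, sep = ","), con)
  }
  invisible(path)
}

#' Read a machine probability panel
#'
#' Checks the probability columns against the label space order and that
#' every row sums to 1 within 1e-6 (rejected rows are named).
#'
#' @param path Panel file written by [write_panel()] (or compatible).
#' @param space A `label_space`.
#' @return List with `panel` (N x C x M, samples ordered by sample_id,
#'   models by model_id), `sample_ids`, `model_ids`.
#' @export
read_panel <- function(path, space) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "model_id", paste0("prob_", space$names))
  if (!identical(names(df), need)) {
    stop("panel file columns must be exactly ",
         paste(need, collapse = ", "), " (label-space order enforced)")
  }
  probs <- as.matrix(df[, paste0("prob_", space$names)])
  rs <- rowSums(probs)
  bad <- which(abs(rs - 1) > 1e-6)
  if (length(bad)) {
    stop("probability row for sample ", df$sample_id[bad[1]], ", model ",
         df$model_id[bad[1]], " sums to ", format(rs[bad[1]]),
         ", not 1")
  }
  ids <- sort(unique(df$sample_id))
  models <- sort(unique(df$model_id))
  panel <- array(NA_real_, c(length(ids), space$C, length(models)),
                 dimnames = list(NULL, space$names, models))
  for (m in seq_along(models)) {
    sub <- df[df$model_id == models[m], ]
    if (nrow(sub) != length(ids)) {
      stop("model ", models[m], " covers ", nrow(sub), " of ",
           length(ids), " samples")
    }
    panel[match(sub$sample_id, ids), , m] <-
      as.matrix(sub[, paste0("prob_", space$names)])
  }
  list(panel = panel, sample_ids = ids, model_ids = models)
}

#' Export a rater profile as key-value text
#'
#' @param profile A `rater_profile`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "rater_profile"))
  sm <- attr(profile$conditional, "smoothing")
  lines <- c(
    paste0("labels: ", paste(profile$space$names, collapse = ",")),
    paste0("n_eval: ", profile$n_eval),
    sprintf("overall_accuracy: %.10f", profile$accuracy),
    paste0("smoothing_mode: ", sm$mode),
    paste0("smoothing_eps: ", sm$eps),
    paste0("fallback_columns: ",
           paste(sm$fallback_columns, collapse = ",")),
    "counts:",
    apply(unclass(profile$confusion), 1L, paste, collapse = ","),
    "conditional:",
    apply(unclass(profile$conditional), 1L, function(v) {
      paste(formatC(v, digits = 12, format = "g"), collapse = ",")
    })
  )
  writeLines(lines, path)
  invisible(path)
}

# cheap deterministic checksum of a canonical JSON string
config_checksum <- function(json) {
  b <- as.integer(charToRaw(json))
  sprintf("%08x", sum(b * (seq_along(b) %% 97 + 1)) %% 4294967291)
}

#' Run the full simulate-profile-fit-evaluate pipeline
#'
#' Drives every module from one configuration: simulates a balanced and an
#' imbalanced cohort sharing a machine profile and a set of raters, writes
#' the ratings/panel files, and runs the probing protocol for every rater
#' and probing size, writing one report per rater per size plus a summary.
#' Every artifact embeds the master seed, the canonical configuration JSON
#' and its checksum, so identical configurations rerun byte-identically.
#'
#' @param config List — or path to a YAML file holding such a list — with
#'   elements `seed` (required), and optionally `n_balanced` (300),
#'   `n_imbalanced` (300), `n_ent` (2), `n_non_ent` (2), `eval_totals`
#'   (c(30, 60, 100, 150)), `folds` (5), `smoothing`, `schemes`, `out`
#'   (output directory, required).
#' @return Invisibly, the summary data frame (also written to
#'   `summary.csv`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config must provide a master seed")
  if (is.null(config$out)) stop("config must provide an output directory")
  defaults <- list(n_balanced = 300L, n_imbalanced = 300L,
                   n_ent = 2L, n_non_ent = 2L,
                   eval_totals = c(30L, 60L, 100L, 150L), folds = 5L,
                   smoothing = "uniform_fallback",
                   schemes = c("HI", "AI", "CavgMH", "PoptMH", "PCoptMH"))
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  # the canonical config covers the analysis parameters, not the output
  # location, so reruns into different directories stay byte-identical
  canon <- config[setdiff(names(config), "out")]
  cfg_json <- jsonlite::toJSON(canon[order(names(canon))],
                               auto_unbox = TRUE, digits = NA)
  stamp <- list(seed = config$seed,
                config = unclass(cfg_json),
                config_checksum = config_checksum(cfg_json))

  space <- otoscopy_labels()
  seed <- as.integer(config$seed)
  raters <- c(
    if (config$n_ent > 0)
      stats::setNames(rater_population(config$n_ent, "ent", seed + 100L),
                      sprintf("ENT%02d", seq_len(config$n_ent))),
    if (config$n_non_ent > 0)
      stats::setNames(rater_population(config$n_non_ent, "non_ent",
                                       seed + 200L),
                      sprintf("GP%02d", seq_len(config$n_non_ent)))
  )
  machine <- machine_preset()
  bal <- simulate_cohort(config$n_balanced, prevalence_spec("balanced"),
                         machine, raters, seed = seed)
  imb <- simulate_cohort(config$n_imbalanced, prevalence_spec("imbalanced"),
                         machine, raters, seed = seed + 50L)

  write_ratings(file.path(out, "ratings_balanced.csv"), bal$truth,
                bal$raters, space)
  write_ratings(file.path(out, "ratings_imbalanced.csv"), imb$truth,
                imb$raters, space)
  write_panel(file.path(out, "panel_balanced.csv"), bal$panel, space)
  write_panel(file.path(out, "panel_imbalanced.csv"), imb$panel, space)

  rows <- list()
  for (r in names(raters)) {
    for (E in config$eval_totals) {
      rep <- probing_protocol(bal, imb, rater = r, eval_total = E,
                              folds = config$folds, seed = seed + 1000L,
                              smoothing = config$smoothing,
                              schemes = config$schemes)
      report <- c(stamp,
                  list(rater = r, eval_total = E,
                       mean_accuracy = as.list(rep$mean),
                       folds = rep$folds, notes = rep$notes))
      jsonlite::write_json(report,
                           file.path(out, sprintf("report_%s_E%03d.json",
                                                  r, E)),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      for (s in names(rep$mean)) {
        rows[[length(rows) + 1L]] <- data.frame(
          rater = r, eval_total = E, scheme = s,
          mean_accuracy = unname(rep$mean[s]))
      }
    }
  }
  summary_df <- do.call(rbind, rows)
  utils::write.csv(summary_df, file.path(out, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(stamp, file.path(out, "run_stamp.json"),
                       auto_unbox = TRUE)
  invisible(summary_df)
}
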