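# On-disk interchange: multi-page TIFF frame stacks with a timestamp sidecar,
# trace / truth / event CSVs, a JSON run manifest, and a transparent JSON
# serialization of fitted trees.

#' Write a synthetic run to disk
#'
#' Frames go to a multi-page 16-bit TIFF plus a CSV of frame timestamps; the
#' trace and ground truth to CSVs (aggregate component diameters joined with
#' `;`); configuration, parameters and seed to a JSON manifest.
#'
#' @param run A `cyto_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(run$frames)[3]
  pages <- lapply(seq_len(n), function(i) {
    clamp(run$frames[, , i], 0, 65535) / 65535
  })
  tiff::writeTIFF(pages, file.path(dir, "frames.tiff"), bits.per.sample = 16L)
  readr::write_csv(tibble(frame = seq_len(n), time_s = run$frame_times_s),
                   file.path(dir, "frame_times.csv"))
  readr::write_csv(run$trace, file.path(dir, "trace.csv"))
  truth <- run$truth
  truth$component_diameters_um <-
    vapply(truth$component_diameters_um,
           function(d) paste(format(d, digits = 10), collapse = ";"), "")
  truth$trajectory <- NULL
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  manifest <- list(run_id = run$run_id,
                   config = unclass(run$config),
                   params = unclass(run$params),
                   classes = run$classes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a frame stack written by [write_run()]
#'
#' @param dir Run directory.
#' @return List with `frames` (rows x cols x n array, grey levels) and
#'   `frame_times_s`.
#' @export
read_frames <- function(dir) {
  pages <- tiff::readTIFF(file.path(dir, "frames.tiff"), all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * 65535
  times <- readr::read_csv(file.path(dir, "frame_times.csv"),
                           show_col_types = FALSE)
  list(frames = frames, frame_times_s = times$time_s)
}

#' Read a trace CSV (time_s + amp_* columns)
#' @param path CSV path.
#' @return Raw trace tibble.
#' @export
read_trace <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  attr(tr, "units") <- "raw"
  tr
}

# ---- tree JSON ------------------------------------------------------------

# flatten an rpart classification tree (no surrogates/competitors) into a
# plain node table: node number, split variable/threshold, children, counts
rpart_node_table <- function(fit) {
  f <- fit$frame
  node <- as.integer(rownames(f))
  k <- length(attr(fit, "ylevels"))
  counts <- f$yval2[, 1 + seq_len(k), drop = FALSE]
  is_leaf <- f$var == "<leaf>"
  sp <- fit$splits
  out <- tibble(node = node, leaf = is_leaf,
                var = NA_character_, threshold = NA_real_,
                left_if_less = NA, n = as.integer(f$n))
  out[paste0("count_", attr(fit, "ylevels"))] <-
    as_tibble(matrix(as.integer(counts), nrow(f), k,
                     dimnames = list(NULL, paste0("count_", attr(fit, "ylevels")))))
  si <- 0L
  for (i in seq_along(node)) {
    if (is_leaf[i]) next
    si <- si + 1L
    out$var[i] <- as.character(f$var[i])
    out$threshold[i] <- unname(sp[si, "index"])
    out$left_if_less[i] <- unname(sp[si, "ncat"]) < 0
  }
  out
}

#' Serialize a fitted tree to JSON
#'
#' Writes the tree as a transparent node table (node id, split variable and
#' threshold, child node ids implied by the CART numbering `2n`/`2n+1`, leaf
#' class counts) together with classes, feature columns and training
#' metadata; no opaque binary objects.
#'
#' @param model A `cyto_tree`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(model, path) {
  obj <- list(classes = model$classes,
              feature_cols = model$feature_cols,
              max_splits = model$max_splits,
              cv_acc = model$cv_acc,
              n_train = model$n_train,
              seed = model$seed,
              training_fingerprint = model$training_fingerprint,
              nodes = rpart_node_table(model$fit))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a JSON-serialized tree
#'
#' @param path JSON path written by [write_tree_json()].
#' @return Object of class `cyto_tree_json`; supports [predict()].
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$nodes <- as_tibble(obj$nodes)
  structure(obj, class = "cyto_tree_json")
}

#' @export
predict.cyto_tree_json <- function(object, newdata, ...) {
  nodes <- object$nodes
  classes <- as.integer(object$classes)
  cc <- paste0("count_", classes)
  lookup <- stats::setNames(seq_len(nrow(nodes)), nodes$node)
  one <- function(row) {
    id <- 1L
    repeat {
      i <- lookup[[as.character(id)]]
      if (nodes$leaf[i]) {
        cnt <- as.numeric(nodes[i, cc])
        return(cnt / sum(cnt))
      }
      x <- row[[nodes$var[i]]]
      goes_left <- if (nodes$left_if_less[i]) x < nodes$threshold[i]
                   else x >= nodes$threshold[i]
      id <- if (goes_left) 2L * id else 2L * id + 1L
    }
  }
  prob <- t(vapply(seq_len(nrow(newdata)),
                   function(r) one(newdata[r, ]), numeric(length(classes))))
  colnames(prob) <- classes
  out <- as_tibble(prob, .name_repair = ~ paste0("prob_", classes))
  out$pred_class <- classes[max.col(prob, ties.method = "first")]
  dplyr::relocate(out, "pred_class")
}

#' Write an evaluation report (metrics CSV + confusion CSV + JSON)
#'
#' @param eval A `cyto_eval`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(eval, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(eval$metrics, file.path(dir, "metrics.csv"))
  cm <- as.data.frame(eval$confusion)
  utils::write.csv(eval$confusion, file.path(dir, "confusion.csv"))
  jsonlite::write_json(list(accuracy = eval$accuracy, n = eval$n,
                            confusion = eval$confusion,
                            metrics = eval$metrics),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
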