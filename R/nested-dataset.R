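#' Canonical group labels of a four-group nested design
#'
#' Two knockout lines, each with its genetically matched control: line A
#' (e.g. a double knockout) and line B (e.g. the same knockout plus an
#' additional ablation). The ratio statistic [statistic_T()] contrasts the
#' control-normalized effect of line A against line B.
#' @export
GROUP_LABELS <- c("control_A", "ko_A", "control_B", "ko_B")

#' Construct a nested measurement dataset
#'
#' A nested dataset holds one scalar measurement per sweep, organized as
#' group > batch (culture) > cell > sweep. It is stored as a data frame with
#' columns `group`, `batch`, `cell`, `sweep`, `value`; `batch` and `cell`
#' labels are scoped within their parent (cell "c1" of batch "b1" and cell
#' "c1" of batch "b2" are different cells).
#'
#' @param x data frame with columns `group`, `batch`, `cell`, `sweep`, `value`.
#' @param single_sweep logical; TRUE for designs with one measurement per cell
#'   (e.g. sucrose-evoked charge) where the sweep resampling level is skipped
#'   by the hierarchical bootstrap.
#' @return an object of class `nested_dataset` (a validated data frame).
#' @seealso [simulate_ephys_dataset()], [statistic_T()], [run_bootstrap()]
#' @export
nested_dataset <- function(x, single_sweep = FALSE) {
  req <- c("group", "batch", "cell", "sweep", "value")
  if (!is.data.frame(x) || !all(req %in% names(x)))
    stop("`x` must be a data frame with columns group, batch, cell, sweep, value",
         call. = FALSE)
  x <- as.data.frame(x)[req]
  x$group <- as.character(x$group)
  bad <- setdiff(unique(x$group), GROUP_LABELS)
  if (length(bad) || !setequal(unique(x$group), GROUP_LABELS))
    stop("dataset must contain exactly the four groups: ",
         paste(GROUP_LABELS, collapse = ", "), call. = FALSE)
  if (!all(is.finite(x$value)))
    stop("all values must be finite", call. = FALSE)
  if (single_sweep) {
    n_per_cell <- tapply(x$value, paste(x$group, x$batch, x$cell), length)
    if (any(n_per_cell != 1L))
      stop("single_sweep = TRUE requires exactly one value per cell", call. = FALSE)
  }
  structure(x, class = c("nested_dataset", "data.frame"),
            single_sweep = single_sweep)
}

#' @export
print.nested_dataset <- function(x, ...) {
  cat("<nested_dataset> ", nrow(x), " sweep values",
      if (isTRUE(attr(x, "single_sweep"))) " (single-sweep design)", "\n", sep = "")
  for (g in GROUP_LABELS) {
    xg <- x[x$group == g, ]
    cat(sprintf("  %-10s %d batches, %d cells, %d values, grand mean %.4g\n", g,
                length(unique(xg$batch)),
                length(unique(paste(xg$batch, xg$cell))),
                nrow(xg), mean(xg$value)))
  }
  invisible(x)
}

# group -> batch -> cell -> numeric sweep vector
as_nested_tree <- function(x) {
  stopifnot(inherits(x, "nested_dataset"))
  lapply(stats::setNames(GROUP_LABELS, GROUP_LABELS), function(g) {
    xg <- x[x$group == g, , drop = FALSE]
    lapply(split(xg, xg$batch, drop = TRUE), function(xb) {
      unname(lapply(split(xb$value, xb$cell, drop = TRUE), as.numeric))
    })
  })
}

#' Read / write a nested dataset as delimited text
#'
#' Tab-separated table with header `group  batch  cell  sweep  value`.
#'
#' @param path file path.
#' @param single_sweep see [nested_dataset()].
#' @return `read_nested_dataset()` returns a `nested_dataset`;
#'   `write_nested_dataset()` returns `path` invisibly.
#' @export
read_nested_dataset <- function(path, single_sweep = FALSE) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  nested_dataset(x, single_sweep = single_sweep)
}

#' @rdname read_nested_dataset
#' @param x a `nested_dataset`.
#' @export
write_nested_dataset <- function(x, path) {
  stopifnot(inherits(x, "nested_dataset"))
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
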