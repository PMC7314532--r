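# Microglial ramification ("dendritic density") index on pre-extracted
# neurite-skeleton summaries. Image segmentation and 3-D reconstruction are
# out of scope; the input is the per-cell summary a reconstruction tool
# exports.

#' Neurite skeleton summary
#'
#' Per-cell branching summary: the branch order of every terminal (a primary
#' process leaving the soma has order 1, each bifurcation increments the
#' order), total process length, and the number of primary processes.
#'
#' @param terminal_orders Positive integers, one per terminal branch.
#' @param total_length Total process length, um, > 0.
#' @param n_primary Number of primary processes, >= 1.
#' @return An object of class `skeleton_summary` (`n_terminals` is derived).
#' @export
skeleton_summary <- function(terminal_orders, total_length, n_primary) {
  if (length(terminal_orders) < 1L || any(terminal_orders < 1) ||
      any(terminal_orders != round(terminal_orders)))
    stop("terminal_orders must be positive integers")
  if (total_length <= 0) stop("total_length must be > 0")
  if (n_primary < 1) stop("n_primary must be >= 1")
  structure(list(terminal_orders = as.integer(terminal_orders),
                 n_terminals = length(terminal_orders),
                 total_length = as.numeric(total_length),
                 n_primary = as.integer(n_primary)),
            class = "skeleton_summary")
}

#' Ramification (dendritic-density) index
#'
#' Scores how densely a cell ramifies its processes in space:
#' `(sum of terminal orders + number of terminals) * (total length / number
#' of primary processes)`. Increasing in branching depth, terminal count and
#' length; decreasing in the number of primaries. Units: um (length-scaled
#' dimensionless branching score).
#'
#' @param s A [skeleton_summary()].
#' @return Numeric index.
#' @export
ramification_index <- function(s) {
  stopifnot(inherits(s, "skeleton_summary"))
  (sum(s$terminal_orders) + s$n_terminals) * (s$total_length / s$n_primary)
}

#' Read skeleton summaries from CSV
#'
#' Expects one row per cell with columns `cell_id`, `terminal_orders`
#' (semicolon-separated integers), `total_length_um`, `n_primary`.
#'
#' @param path CSV file path.
#' @return Named list of [skeleton_summary()] objects.
#' @export
read_skeletons_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    skeleton_summary(as.integer(strsplit(df$terminal_orders[i], ";")[[1]]),
                     df$total_length_um[i], df$n_primary[i]))
  names(out) <- df$cell_id
  out
}

#' Tabulate ramification indices per cell
#'
#' @param skeletons Named list of [skeleton_summary()] objects.
#' @param groups Optional character vector of group labels (recycled named by
#'   cell).
#' @return data.frame with `cell_id`, optional `group`, and `index`.
#' @export
ramification_table <- function(skeletons, groups = NULL) {
  idx <- vapply(skeletons, ramification_index, 0)
  out <- data.frame(cell_id = names(skeletons) %||% seq_along(skeletons),
                    index = unname(idx), stringsAsFactors = FALSE)
  if (!is.null(groups)) out$group <- groups
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
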