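# Centerline file format: `<stem>.ctl.tsv` (one node per line) plus a
# sidecar `<stem>.ctl.json` with case metadata. Plain text, '.' decimal
# separator, fixed 6-decimal formatting so round-trips are byte-identical.

#' Write a centerline tree to a `.ctl.tsv` file (+ `.ctl.json` sidecar)
#'
#' @param tree A `centerline_tree`.
#' @param stem Path stem; `<stem>.ctl.tsv` and `<stem>.ctl.json` are written.
#' @return The TSV path, invisibly.
#' @export
write_centerline <- function(tree, stem) {
  tsv <- paste0(stem, ".ctl.tsv")
  jsn <- paste0(stem, ".ctl.json")
  n <- nrow(tree$nodes)
  lines <- c(
    "case_id\tnode_id\tparent_id\tx\ty\tradius\tbranch_label\tside",
    sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s",
            tree$case_id, seq_len(n), tree$parent,
            fmt_num(tree$nodes[, 1]), fmt_num(tree$nodes[, 2]),
            fmt_num(tree$radius), tree$branch, tree$side))
  writeLines(lines, tsv, useBytes = TRUE)
  meta <- list(case_id = tree$case_id, seed = tree$seed,
               side = tree$side, params = tree$params)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), jsn, useBytes = TRUE)
  invisible(tsv)
}

#' Read a centerline tree written by [write_centerline()]
#'
#' @param tsv Path to the `.ctl.tsv` file; the `.ctl.json` sidecar is read
#'   from the same stem if present.
#' @return A `centerline_tree`.
#' @export
read_centerline <- function(tsv) {
  df <- utils::read.delim(tsv, colClasses = c(
    case_id = "character", node_id = "integer", parent_id = "integer",
    x = "numeric", y = "numeric", radius = "numeric",
    branch_label = "character", side = "character"))
  jsn <- sub("\\.ctl\\.tsv$", ".ctl.json", tsv)
  meta <- if (file.exists(jsn)) jsonlite::fromJSON(jsn) else NULL
  tree <- structure(
    list(nodes = unname(cbind(df$x, df$y)), parent = df$parent_id,
         radius = df$radius, branch = df$branch_label, side = df$side[1],
         case_id = df$case_id[1],
         seed = if (!is.null(meta)) as.integer(meta$seed) else NA_integer_,
         params = if (!is.null(meta)) meta$params else NULL),
    class = "centerline_tree")
  validate_tree(tree)
  tree
}

#' Generate a cohort of synthetic cases
#'
#' Alternates left/right sides across cases (mirrored parameterizations) and
#' derives one sub-seed per case from `seed`. The default cohort size of 12
#' with a 10/2 train/test split mirrors an 80/20 protocol.
#'
#' @param n_cases Number of trees.
#' @param seed Master seed.
#' @param params Base parameters from [tree_params()]; `side` is overridden
#'   per case.
#' @return List of `centerline_tree` objects.
#' @export
generate_case_set <- function(n_cases = 12L, seed = 1L,
                              params = tree_params()) {
  lapply(seq_len(n_cases), function(i) {
    p <- params
    p$side <- if (i %% 2L == 1L) "right" else "left"
    generate_tree(p, seed = (seed * 1009L + i) %% 2147483647L,
                  case_id = sprintf("case_%02d", i))
  })
}

#' Split a case set into train and test cases
#'
#' @param trees List of trees from [generate_case_set()].
#' @param n_test Number of held-out test cases (default 2, taken from the
#'   end of the list so both sides are represented).
#' @return List with `train` and `test` tree lists.
#' @export
split_cases <- function(trees, n_test = 2L) {
  n <- length(trees)
  stopifnot(n_test < n)
  list(train = trees[seq_len(n - n_test)],
       test = trees[seq(n - n_test + 1L, n)])
}
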