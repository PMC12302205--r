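# Train/validation/test partitioning policies. All three policies produce a
# 6:1:1 split by default; the extreme-HFE and scaffold policies probe
# out-of-distribution generalization. Splits are computed on the pre-filter
# dataset; the uncertainty / single-heavy-atom filters are applied to each
# partition afterwards (see filter_split), so filtered and unfiltered
# evaluations share the same membership.

# run code under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.new_split <- function(train, val, test, policy, seed, metadata = list()) {
  structure(list(train_ids = train, val_ids = val, test_ids = test,
                 policy = policy, seed = seed, metadata = metadata),
            class = "sc_split")
}

#' @export
print.sc_split <- function(x, ...) {
  cat("<data split> policy =", x$policy, " seed =", x$seed, "\n",
      " train/val/test =", length(x$train_ids), "/", length(x$val_ids), "/",
      length(x$test_ids), "\n")
  invisible(x)
}

# allocate `ids` (already shuffled) to partitions proportionally to ratios,
# floors first, leftovers round-robin train -> val -> test
.allocate <- function(ids, ratios) {
  s <- length(ids)
  base <- floor(s * ratios / sum(ratios))
  leftover <- s - sum(base)
  if (leftover > 0L) {
    extra <- rep(seq_along(ratios), length.out = leftover)
    for (p in extra) base[p] <- base[p] + 1L
  }
  ends <- cumsum(base)
  starts <- c(1L, ends[-length(ends)] + 1L)
  lapply(seq_along(ratios), function(p) {
    if (base[p] == 0L) character(0L) else ids[starts[p]:ends[p]]
  })
}

#' Stratified random split by HFE
#'
#' Records are binned into `n_bins` quantile bins of the experimental HFE so
#' that every partition samples the full HFE range; within each bin, members
#' are shuffled (seeded) and allocated to train/validation/test proportionally
#' to `ratios`, with per-bin leftovers assigned round-robin
#' train, then validation, then test. With the default 6:1:1 ratios the
#' partition sizes match the exact targets to within `n_bins` records.
#'
#' @param records An `sc_records` data frame.
#' @param ratios Positive weights for train/validation/test (default 6:1:1).
#' @param n_bins Number of quantile strata (default 8).
#' @param seed Integer RNG seed; same seed, same split.
#' @returns An `sc_split` with `train_ids`, `val_ids`, `test_ids`, `policy`,
#'   `seed` and `metadata` (the bin edges).
#' @export
stratified_split <- function(records, ratios = c(6, 1, 1), n_bins = 8L,
                             seed = 1L) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (nrow(records) < length(ratios)) {
    stop("fewer records (", nrow(records), ") than partitions")
  }
  if (nrow(records) < n_bins) stop("fewer records than bins")
  hfe <- records$expt_hfe
  breaks <- unique(stats::quantile(hfe, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(breaks) < 2L) rep(1L, nrow(records))
         else as.integer(cut(hfe, breaks, include.lowest = TRUE))
  parts <- rep(list(character(0L)), length(ratios))
  .with_seed(seed, {
    for (b in sort(unique(bin))) {
      ids <- sort(records$id[bin == b])   # id order first, then seeded shuffle
      ids <- sample(ids)
      alloc <- .allocate(ids, ratios)
      for (p in seq_along(parts)) parts[[p]] <- c(parts[[p]], alloc[[p]])
    }
  })
  while (length(parts) < 3L) parts <- c(parts, list(character(0L)))
  .new_split(parts[[1L]], parts[[2L]], parts[[3L]], "stratified", seed,
             metadata = list(n_bins = n_bins, bin_edges = unname(breaks)))
}

#' Extreme-HFE split (out-of-distribution by magnitude)
#'
#' The `test_size` records of largest |experimental HFE| form the test set
#' (ties at the cutoff broken by ascending compound id); the remaining
#' records are divided into train and validation at 6:1 using the stratified
#' binning. By construction every test |HFE| is at least as large as every
#' train/validation |HFE|.
#'
#' @param records An `sc_records` data frame.
#' @param test_size Number of test molecules (default 80).
#' @param n_bins Strata used for the train/validation division.
#' @param seed Integer RNG seed.
#' @returns An `sc_split`; `metadata$abs_hfe_cutoff` records the smallest
#'   |HFE| in the test set.
#' @export
hfe_extreme_split <- function(records, test_size = 80L, n_bins = 8L,
                              seed = 1L) {
  if (test_size <= 0L || test_size >= nrow(records)) {
    stop("test_size must be in (0, number of records)")
  }
  ord <- order(-abs(records$expt_hfe), records$id)
  test_ids <- records$id[ord[seq_len(test_size)]]
  rest <- records[!records$id %in% test_ids, , drop = FALSE]
  inner <- stratified_split(.as_records(rest), ratios = c(6, 1),
                            n_bins = min(n_bins, nrow(rest)), seed = seed)
  .new_split(inner$train_ids, inner$val_ids, test_ids, "hfe_extreme", seed,
             metadata = list(
               abs_hfe_cutoff = min(abs(records$expt_hfe[records$id %in% test_ids])),
               n_bins = n_bins
             ))
}

#' Scaffold split (out-of-distribution by chemotype)
#'
#' Molecules are grouped by Bemis-Murcko scaffold. Acyclic molecules (empty
#' scaffold) are shuffled and distributed 6:1:1. Scaffold groups are assigned
#' whole — largest group first, ties by scaffold string — to whichever
#' partition is currently furthest below its 6:1:1 target among
#' ring-containing molecules, so no scaffold ever spans two partitions.
#'
#' @param records An `sc_records` data frame.
#' @param ratios Positive weights for train/validation/test (default 6:1:1).
#' @param seed Integer RNG seed (acyclic shuffle only).
#' @returns An `sc_split`; `metadata$scaffold` maps each id to its scaffold
#'   string (`""` for acyclic molecules).
#' @export
scaffold_split <- function(records, ratios = c(6, 1, 1), seed = 1L) {
  if (any(ratios <= 0)) stop("ratios must be positive")
  scaf <- vapply(records$smiles, murcko_scaffold, character(1L),
                 USE.NAMES = FALSE)
  names(scaf) <- records$id
  acyclic <- records$id[scaf == ""]
  parts <- .with_seed(seed, .allocate(sample(sort(acyclic)), ratios))

  ring_ids <- records$id[scaf != ""]
  n_ring <- length(ring_ids)
  if (n_ring > 0L) {
    groups <- split(ring_ids, scaf[ring_ids])
    sizes <- vapply(groups, length, 1L)
    ord <- order(-sizes, names(groups))
    target <- n_ring * ratios / sum(ratios)
    current <- numeric(length(ratios))
    for (g in ord) {
      deficit <- target - current
      p <- which.max(deficit)          # ties resolve train > val > test
      parts[[p]] <- c(parts[[p]], groups[[g]])
      current[p] <- current[p] + sizes[g]
    }
  }
  .new_split(parts[[1L]], parts[[2L]], parts[[3L]], "scaffold", seed,
             metadata = list(scaffold = as.list(scaf)))
}

#' Apply record filters to each partition of a split
#'
#' Mirrors the protocol of splitting before filtering: partition membership is
#' fixed first, then the uncertainty / single-heavy-atom filters shrink each
#' partition independently.
#'
#' @param split An `sc_split`.
#' @param ... `sc_filter_report` objects (ids kept by all survive).
#' @returns A new `sc_split` with filtered id sets.
#' @export
filter_split <- function(split, ...) {
  reports <- list(...)
  keep <- function(ids) {
    for (r in reports) ids <- ids[ids %in% r$kept]
    ids
  }
  .new_split(keep(split$train_ids), keep(split$val_ids), keep(split$test_ids),
             split$policy, split$seed, split$metadata)
}

#' Extract the records of each split partition
#'
#' @param records An `sc_records` data frame.
#' @param split An `sc_split`.
#' @returns A list of three `sc_records` data frames: `train`, `val`, `test`.
#' @export
split_records <- function(records, split) {
  take <- function(ids) {
    out <- records[match(ids, records$id), , drop = FALSE]
    if (anyNA(out$id)) stop("split refers to ids absent from records")
    rownames(out) <- NULL
    attr(out, "structures") <- attr(records, "structures")
    .as_records(out)
  }
  list(train = take(split$train_ids), val = take(split$val_ids),
       test = take(split$test_ids))
}

#' Write a split as JSON and/or CSV
#'
#' @param split An `sc_split`.
#' @param json Optional JSON output path (ids per partition, policy, seed,
#'   metadata).
#' @param csv Optional two-column CSV output path (id, partition).
#' @returns `split`, invisibly.
#' @export
write_split <- function(split, json = NULL, csv = NULL) {
  if (!is.null(json)) {
    jsonlite::write_json(list(
      policy = split$policy, seed = split$seed,
      train_ids = split$train_ids, val_ids = split$val_ids,
      test_ids = split$test_ids, metadata = split$metadata
    ), json, auto_unbox = TRUE)
  }
  if (!is.null(csv)) {
    df <- data.frame(
      id = c(split$train_ids, split$val_ids, split$test_ids),
      partition = c(rep("train", length(split$train_ids)),
                    rep("val", length(split$val_ids)),
                    rep("test", length(split$test_ids))),
      stringsAsFactors = FALSE
    )
    utils::write.csv(df, csv, row.names = FALSE)
  }
  invisible(split)
}
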