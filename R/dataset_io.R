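# FreeSolv-dialect dataset IO and record-level filters.
#
# A record set is a data.frame (class "sc_records") with columns
#   id, smiles, name, expt_hfe, expt_uncertainty, calc_hfe, calc_uncertainty,
#   n_heavy
# plus one column "phys_<model>" per attached physics model, and an optional
# "structures" attribute: a named list (id -> data.frame(element, x, y, z,
# charge)) carrying 3D structures read from SDF/MOL2 files.

.as_records <- function(df) {
  class(df) <- c("sc_records", "data.frame")
  df
}

#' Parse a FreeSolv-dialect database file
#'
#' Reads the semicolon-delimited text dialect used by the FreeSolv database
#' (v0.52 layout): lines starting with `#` are header comments; each data line
#' carries at least seven fields — compound id, SMILES, name, experimental
#' HFE (kcal/mol), experimental uncertainty, calculated HFE, calculated
#' uncertainty — with any trailing reference/note fields ignored. Every SMILES
#' is parsed and validated against the supported element vocabulary at read
#' time, so downstream featurization is total.
#'
#' @param file Path to the database file, or `NULL` if `text` is given.
#' @param text Optional character vector of raw lines (overrides `file`).
#' @returns An `sc_records` data frame, one row per data line, in file order.
#' @examples
#' txt <- c("# comment", "mol_a; CCO; ethanol; -5.0; 0.6; -4.2; 0.02; r1; r2")
#' parse_freesolv(text = txt)
#' @export
parse_freesolv <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either file or text must be given")
    text <- readLines(file, warn = FALSE)
  }
  keep <- !grepl("^\\s*#", text) & nzchar(trimws(text))
  lineno <- which(keep)
  lines <- text[keep]
  n <- length(lines)
  if (n == 0L) {
    return(.as_records(data.frame(
      id = character(), smiles = character(), name = character(),
      expt_hfe = numeric(), expt_uncertainty = numeric(),
      calc_hfe = numeric(), calc_uncertainty = numeric(),
      n_heavy = integer(), stringsAsFactors = FALSE
    )))
  }
  parts <- strsplit(lines, ";", fixed = TRUE)
  num <- function(x, what, ln) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("line ", ln, ": non-numeric ", what, " field '", x, "'")
    v
  }
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    p <- trimws(parts[[k]])
    if (length(p) < 7L) {
      stop("line ", lineno[k], ": expected at least 7 semicolon-delimited ",
           "fields, found ", length(p))
    }
    rows[[k]] <- data.frame(
      id = p[1L], smiles = p[2L], name = p[3L],
      expt_hfe = num(p[4L], "experimental HFE", lineno[k]),
      expt_uncertainty = num(p[5L], "experimental uncertainty", lineno[k]),
      calc_hfe = num(p[6L], "calculated HFE", lineno[k]),
      calc_uncertainty = num(p[7L], "calculated uncertainty", lineno[k]),
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  if (anyDuplicated(df$id)) {
    stop("duplicate compound id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (any(df$expt_uncertainty < 0)) {
    stop("negative experimental uncertainty for id(s): ",
         paste(df$id[df$expt_uncertainty < 0], collapse = ", "))
  }
  df$n_heavy <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(heavy_atom_count(df$smiles[i]), error = function(e) {
      stop("record '", df$id[i], "': ", conditionMessage(e), call. = FALSE)
    })
  }, integer(1L))
  .as_records(df)
}

#' Serialize records back to the FreeSolv text dialect
#'
#' Writes the seven parsed fields per record (id, SMILES, name, experimental
#' HFE and uncertainty, calculated HFE and uncertainty), so that
#' `parse_freesolv(write_freesolv(x))` is the identity on those fields.
#'
#' @param records An `sc_records` data frame.
#' @param file Output path; when `NULL` the lines are returned invisibly.
#' @returns The character vector of written lines, invisibly.
#' @export
write_freesolv <- function(records, file = NULL) {
  header <- paste("# compound id (and file prefix); SMILES; iupac name (or",
                  "alternative); experimental value (kcal/mol);",
                  "experimental uncertainty (kcal/mol); calculated value",
                  "(kcal/mol); calculated uncertainty (kcal/mol)")
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  lines <- c(header, paste(
    records$id, records$smiles, records$name, fmt(records$expt_hfe),
    fmt(records$expt_uncertainty), fmt(records$calc_hfe),
    fmt(records$calc_uncertainty), sep = "; "
  ))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

.filter_report <- function(ids, removed_ids, reason) {
  stopifnot(all(removed_ids %in% ids))
  structure(list(
    kept = setdiff(ids, removed_ids),
    removed = data.frame(id = removed_ids,
                         reason = rep_len(reason, length(removed_ids)),
                         stringsAsFactors = FALSE)
  ), class = "sc_filter_report")
}

#' @export
print.sc_filter_report <- function(x, ...) {
  cat("<filter report> kept", length(x$kept), "removed", nrow(x$removed), "\n")
  if (nrow(x$removed) > 0L) print(table(x$removed$reason))
  invisible(x)
}

#' Filter out records with high experimental uncertainty
#'
#' Implements the low-uncertainty selection rule: a record with
#' |HFE| < 6 kcal/mol is removed iff its uncertainty exceeds 0.6 kcal/mol; a
#' record with |HFE| >= 6 kcal/mol is removed iff its relative uncertainty
#' exceeds 10%. Both boundaries are kept (the rule is "greater than", strict).
#'
#' @param records An `sc_records` data frame.
#' @param abs_threshold Absolute uncertainty cutoff, kcal/mol (default 0.6).
#' @param rel_threshold Relative uncertainty cutoff (default 0.10).
#' @param hfe_cut |HFE| above which the relative rule applies (default 6).
#' @returns An `sc_filter_report`: `kept` (ids) and `removed` (id, reason).
#' @export
filter_low_uncertainty <- function(records, abs_threshold = 0.6,
                                   rel_threshold = 0.10, hfe_cut = 6) {
  a <- abs(records$expt_hfe)
  u <- records$expt_uncertainty
  removed <- ifelse(a < hfe_cut, u > abs_threshold, u / a > rel_threshold)
  .filter_report(records$id, records$id[removed], "high_uncertainty")
}

#' Filter out single-heavy-atom molecules
#'
#' Molecules whose graph has a single node (e.g. methane, hydrogen sulfide,
#' ammonia) cannot be processed by the message-passing architecture and are
#' removed from the modeled dataset.
#'
#' @param records An `sc_records` data frame.
#' @returns An `sc_filter_report`.
#' @export
drop_single_heavy_atom <- function(records) {
  removed <- records$n_heavy == 1L
  .filter_report(records$id, records$id[removed], "single_heavy_atom")
}

#' Subset records to the kept set of one or more filter reports
#'
#' @param records An `sc_records` data frame.
#' @param ... One or more `sc_filter_report` objects; a record survives iff it
#'   is kept by all of them.
#' @returns The filtered `sc_records` data frame (order preserved).
#' @export
apply_filters <- function(records, ...) {
  reports <- list(...)
  keep <- rep(TRUE, nrow(records))
  for (r in reports) {
    stopifnot(inherits(r, "sc_filter_report"))
    keep <- keep & records$id %in% r$kept
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  .as_records(out)
}

#' Write a filter report as JSON
#'
#' @param report An `sc_filter_report`.
#' @param file Output path.
#' @returns `file`, invisibly.
#' @export
write_filter_report <- function(report, file) {
  jsonlite::write_json(list(kept = report$kept, removed = report$removed),
                       file, auto_unbox = FALSE)
  invisible(file)
}

#' Attach physics-model predictions to records
#'
#' Adds a column `phys_<model_name>` with the supplied per-id predicted HFEs
#' (kcal/mol). Records absent from the table keep `NA`; every id in the table
#' must exist among the records, and duplicated table ids are an error.
#'
#' @param records An `sc_records` data frame.
#' @param table A data frame with columns `id` and `value` (kcal/mol), or a
#'   named numeric vector, or a path to a two-column CSV with a header.
#' @param model_name Name of the physics model (column suffix).
#' @returns The augmented `sc_records` data frame.
#' @export
attach_physics_predictions <- function(records, table, model_name) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
    names(table)[1:2] <- c("id", "value")
  }
  if (is.numeric(table) && !is.null(names(table))) {
    table <- data.frame(id = names(table), value = unname(table),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table), all(c("id", "value") %in% names(table)))
  if (anyDuplicated(table$id)) {
    stop("duplicate id(s) in physics table: ",
         paste(unique(table$id[duplicated(table$id)]), collapse = ", "))
  }
  unknown <- setdiff(table$id, records$id)
  if (length(unknown) > 0L) {
    stop("physics table contains id(s) not present in records: ",
         paste(unknown, collapse = ", "))
  }
  col <- paste0("phys_", model_name)
  if (!col %in% names(records)) records[[col]] <- NA_real_
  records[[col]][match(table$id, records$id)] <- table$value
  .as_records(records)
}

#' Extract one physics prediction column
#'
#' The packaged explicit-solvent calculated column (`calc_hfe`) and
#' user-attached tables are interchangeable sources of the physics baseline.
#'
#' @param records An `sc_records` data frame.
#' @param model_name A name previously used with
#'   [attach_physics_predictions()], or `"calc"` for the packaged column.
#' @returns Named numeric vector of predictions (kcal/mol), names = ids.
#' @export
physics_predictions <- function(records, model_name = "calc") {
  col <- if (model_name == "calc") "calc_hfe" else paste0("phys_", model_name)
  if (!col %in% names(records)) {
    stop("no physics predictions named '", model_name, "' attached")
  }
  stats::setNames(records[[col]], records$id)
}

#' Summary statistics of a FreeSolv-style record set
#'
#' Computes the dataset descriptors used to characterize an HFE database:
#' record counts before/after the uncertainty and single-heavy-atom filters,
#' the count of records at a given default uncertainty value, HFE and
#' uncertainty moments and ranges, heavy-atom statistics, acyclic vs
#' ring-containing counts, and the RMSE of the packaged calculated column
#' against experiment.
#'
#' @param records An `sc_records` data frame.
#' @param default_uncertainty Value whose exact-match count is reported
#'   (kcal/mol; 0.6 is the database's default label).
#' @returns A named list of statistics.
#' @export
freesolv_statistics <- function(records, default_uncertainty = 0.6) {
  unc <- filter_low_uncertainty(records)
  single <- drop_single_heavy_atom(records)
  low <- apply_filters(records, unc, single)
  ring <- vapply(records$smiles,
                 function(s) any(parse_smiles(s)$ring_bond), TRUE,
                 USE.NAMES = FALSE)
  list(
    n_records = nrow(records),
    n_low_uncertainty_subset = nrow(low),
    n_removed_uncertainty = sum(unc$removed$reason == "high_uncertainty"),
    n_removed_single_heavy_atom = nrow(single$removed),
    n_default_uncertainty = sum(records$expt_uncertainty == default_uncertainty),
    mean_hfe = mean(records$expt_hfe),
    sd_hfe = stats::sd(records$expt_hfe),
    min_hfe = min(records$expt_hfe),
    max_hfe = max(records$expt_hfe),
    mean_uncertainty = mean(records$expt_uncertainty),
    mean_heavy_atoms = mean(records$n_heavy),
    n_acyclic = sum(!ring),
    n_ring = sum(ring),
    rmse_calc_vs_expt = sqrt(mean((records$calc_hfe - records$expt_hfe)^2))
  )
}

# ---------------------------------------------------------------------------
# structure files (SDF V2000 / MOL2), matched to records by filename stem

.read_sdf_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("truncated SDF file: ", path)
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  if (is.na(na) || na < 1L) stop("cannot parse SDF counts line in: ", path)
  atoms <- lines[5:(4L + na)]
  el <- trimws(substr(atoms, 32L, 34L))
  data.frame(
    element = el,
    x = as.numeric(substr(atoms, 1L, 10L)),
    y = as.numeric(substr(atoms, 11L, 20L)),
    z = as.numeric(substr(atoms, 21L, 30L)),
    charge = NA_real_,
    stringsAsFactors = FALSE
  )
}

.read_mol2_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^@<TRIPOS>ATOM", lines)
  if (length(start) == 0L) stop("no @<TRIPOS>ATOM section in: ", path)
  end <- grep("^@<TRIPOS>", lines)
  end <- end[end > start[1L]]
  last <- if (length(end) > 0L) end[1L] - 1L else length(lines)
  rows <- lines[(start[1L] + 1L):last]
  rows <- rows[nzchar(trimws(rows))]
  parts <- strsplit(trimws(rows), "\\s+")
  data.frame(
    element = vapply(parts, function(p) sub("\\..*$", "", p[6L]), character(1L)),
    x = vapply(parts, function(p) as.numeric(p[3L]), 1),
    y = vapply(parts, function(p) as.numeric(p[4L]), 1),
    z = vapply(parts, function(p) as.numeric(p[5L]), 1),
    charge = vapply(parts, function(p) {
      if (length(p) >= 9L) as.numeric(p[9L]) else NA_real_
    }, 1),
    stringsAsFactors = FALSE
  )
}

#' Attach 3D structures from SDF/MOL2 files
#'
#' Files are matched to records by filename stem (the compound id). The
#' heavy-atom count of each structure must equal the heavy-atom count of the
#' record's SMILES; hydrogens may be present in the file and are retained for
#' charge condensation.
#'
#' @param records An `sc_records` data frame.
#' @param files Character vector of `.sdf` / `.mol2` paths.
#' @returns `records` with a `structures` attribute (named list of atom
#'   tables with columns element, x, y, z, charge).
#' @export
attach_structures <- function(records, files) {
  structures <- attr(records, "structures")
  if (is.null(structures)) structures <- list()
  for (f in files) {
    id <- sub("\\.(sdf|mol2)$", "", basename(f), ignore.case = TRUE)
    if (!id %in% records$id) {
      stop("structure file '", f, "' does not match any record id")
    }
    tab <- if (grepl("\\.sdf$", f, ignore.case = TRUE)) .read_sdf_coords(f)
           else .read_mol2_coords(f)
    n_heavy <- sum(tab$element != "H")
    expected <- records$n_heavy[records$id == id]
    if (n_heavy != expected) {
      stop("structure '", f, "' has ", n_heavy, " heavy atoms but SMILES of '",
           id, "' has ", expected)
    }
    structures[[id]] <- tab
  }
  attr(records, "structures") <- structures
  .as_records(records)
}

#' Write records as CSV
#'
#' @param records An `sc_records` data frame.
#' @param file Output path.
#' @returns `file`, invisibly.
#' @export
write_records_csv <- function(records, file) {
  utils::write.csv(as.data.frame(records), file, row.names = FALSE)
  invisible(file)
}
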