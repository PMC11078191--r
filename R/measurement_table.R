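# Per-residue measurement tables: the fit targets of the GAF analysis.
#
# A measurement table is a data.frame with one row per residue and columns
#   residue   integer residue number (unique)
#   resname   3-letter code (optional)
#   segment   segment label (optional)
# plus any subset of the observable/uncertainty pairs
#   S_CaHa / S_CaHa_err, S_NCa / S_NCa_err, R1 / R1_err, R1rho / R1rho_err
# Rates are s^-1; order parameters are unitless.

.obs_cols <- c("S_CaHa", "S_NCa", "R1", "R1rho")

#' Validate a measurement table
#'
#' Enforces the table invariants: unique residue numbers, strictly positive
#' uncertainties, non-negative rates, order parameters in \[0, 1.1\] (values
#' slightly above 1 are tolerated as noise and flagged in the
#' `"flagged_gt1"` attribute).
#'
#' @param tab data.frame, see package conventions above.
#' @return the validated table (invisibly), with a `flagged_gt1` attribute
#'   listing residues whose order parameter exceeds 1.
#' @export
validate_measurement_table <- function(tab) {
  if (!"residue" %in% names(tab))
    stop("format error: measurement table has no 'residue' column")
  if (anyDuplicated(tab$residue))
    stop("validation error: duplicated residue numbers: ",
         paste(unique(tab$residue[duplicated(tab$residue)]), collapse = ", "))
  present <- intersect(.obs_cols, names(tab))
  if (length(present) == 0)
    stop("format error: no observable column among ",
         paste(.obs_cols, collapse = ", "))
  for (cn in present) {
    ec <- paste0(cn, "_err")
    if (ec %in% names(tab)) {
      bad <- which(!is.na(tab[[ec]]) & tab[[ec]] <= 0)
      if (length(bad))
        stop("validation error: non-positive uncertainty in ", ec,
             " for residue(s) ", paste(tab$residue[bad], collapse = ", "))
    }
    if (cn %in% c("R1", "R1rho")) {
      bad <- which(!is.na(tab[[cn]]) & tab[[cn]] < 0)
      if (length(bad))
        stop("validation error: negative rate in ", cn, " for residue(s) ",
             paste(tab$residue[bad], collapse = ", "))
    } else {
      bad <- which(!is.na(tab[[cn]]) & (tab[[cn]] < 0 | tab[[cn]] > 1.1))
      if (length(bad))
        stop("validation error: order parameter ", cn, " outside [0, 1.1] ",
             "for residue(s) ", paste(tab$residue[bad], collapse = ", "))
    }
  }
  flagged <- integer(0)
  for (cn in intersect(c("S_CaHa", "S_NCa"), names(tab)))
    flagged <- union(flagged, tab$residue[!is.na(tab[[cn]]) & tab[[cn]] > 1])
  attr(tab, "flagged_gt1") <- flagged
  invisible(tab)
}

#' Read a per-residue measurement table
#'
#' Reads a TSV (or CSV) of per-residue observables. Columns can be renamed
#' through `col_map`; unknown columns are preserved untouched as annotations.
#'
#' @param path file path.
#' @param col_map optional named character vector mapping file column names
#'   to canonical names, e.g. `c(res = "residue", S = "S_CaHa")`.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return a validated measurement table (data.frame).
#' @export
read_measurement_table <- function(path, col_map = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(tab))
    names(tab)[idx[!is.na(idx)]] <- col_map[!is.na(idx)]
  }
  tab <- validate_measurement_table(tab)
  tab
}

#' @rdname read_measurement_table
#' @param tab measurement table to write.
#' @return `write_measurement_table`: the path, invisibly.
#' @export
write_measurement_table <- function(tab, path, sep = "\t") {
  # 9 significant digits keeps read/write round trips value-stable
  out <- tab
  num <- vapply(out, is.numeric, logical(1)) & !(names(out) == "residue")
  out[num] <- lapply(out[num], function(x) signif(x, 9))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
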