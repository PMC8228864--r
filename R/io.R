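#' Read and write rectangular PK datasets (NONMEM dialect)
#'
#' Event/observation tables in the NONMEM data-stream convention: one row per
#' dose or observation with columns `ID, TIME, AMT, DV, CMT, EVID, MDV` plus
#' covariates.  Dose rows have `EVID = 1`, `MDV = 1` and missing `DV`;
#' observation rows have `EVID = 0`, `MDV = 0` and missing `AMT`.  Missing
#' values are written as `"."`.  Lines starting with `#` are provenance
#' comments and are skipped on read.
#'
#' @param path CSV file path.
#' @param ds an `nm_dataset` data.frame (for writing).
#' @param comment optional character vector of provenance lines to embed
#'   (written as `# ...` headers).
#' @return `read_nm_dataset()` returns a validated `nm_dataset` data.frame.
#' @export
read_nm_dataset <- function(path) {
  ds <- utils::read.csv(path, na.strings = ".", comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("ID", "TIME", "DV", "AMT", "EVID")
  miss <- setdiff(need, names(ds))
  if (length(miss)) stop("dataset missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"MDV" %in% names(ds)) ds$MDV <- as.integer(is.na(ds$DV))
  validate_nm_dataset(ds)
  structure(ds, class = c("nm_dataset", "data.frame"))
}

#' @rdname read_nm_dataset
#' @export
write_nm_dataset <- function(ds, path, comment = NULL) {
  validate_nm_dataset(ds)
  out <- as.data.frame(ds)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  # write with "." for NA, plain CSV otherwise
  txt <- utils::capture.output(
    utils::write.csv(out, row.names = FALSE, quote = FALSE, na = "."))
  writeLines(txt, con)
  invisible(path)
}

validate_nm_dataset <- function(ds) {
  bad <- list()
  dose <- ds$EVID == 1
  obs <- ds$EVID == 0
  if (any(dose & !is.na(ds$DV))) {
    bad <- c(bad, paste("dose rows with DV present:",
                        paste(which(dose & !is.na(ds$DV)), collapse = ",")))
  }
  if (any(dose & (is.na(ds$AMT) | ds$AMT <= 0))) {
    bad <- c(bad, "dose rows need AMT > 0")
  }
  if (any(obs & !is.na(ds$AMT))) {
    bad <- c(bad, paste("observation rows with AMT present:",
                        paste(which(obs & !is.na(ds$AMT)), collapse = ",")))
  }
  if ("MDV" %in% names(ds) && any(obs & ds$MDV != 0 & !is.na(ds$DV))) {
    bad <- c(bad, "observation rows with DV must have MDV = 0")
  }
  tm <- tapply(ds$TIME, ds$ID, function(x) all(diff(x) >= 0))
  if (!all(unlist(tm))) {
    bad <- c(bad, paste("TIME not non-decreasing within ID:",
                        paste(names(tm)[!unlist(tm)], collapse = ",")))
  }
  if (length(bad)) stop("invalid dataset: ", paste(bad, collapse = "; "))
  invisible(ds)
}

#' Convert concentrations between mg/L and ng/mL
#'
#' Internal computations use mg/L; assay reports are conventionally ng/mL
#' (1 mg/L = 1000 ng/mL).  Display-layer helper only.
#'
#' @param x concentration values.
#' @param to `"ng/mL"` or `"mg/L"`.
#' @return Converted values.
#' @export
convert_conc <- function(x, to = c("ng/mL", "mg/L")) {
  to <- match.arg(to)
  if (to == "ng/mL") x * 1000 else x / 1000
}
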