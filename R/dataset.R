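DVID_VOCAB <- c("mrna", "pcc", "2mc", "3hp", "c3c2")

DATASET_COLS <- c("id", "time", "evid", "amt", "rate", "dv", "dvid", "mdv",
                  "blq", "lloq", "wt", "species")

#' Validate a long-format PK/PD dataset
#'
#' Enforces the NONMEM-convention contract: dose records have `evid = 1` and
#' `mdv = 1`; observation records have `evid = 0` and a `dv`; `blq = 1`
#' requires an `lloq`; times are non-negative and sorted within subject;
#' `dvid` is drawn from the controlled vocabulary.
#'
#' @param d a data.frame with the columns listed under [read_dataset()].
#' @return The dataset, classed `pkpd_dataset`, invisibly valid.
#' @export
validate_dataset <- function(d) {
  missing_cols <- setdiff(DATASET_COLS, names(d))
  if (length(missing_cols)) {
    stop("dataset is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) stop(sprintf("dataset row %d: %s", i[1], msg))
  }
  bad(!d$evid %in% c(0L, 1L), "evid must be 0 or 1")
  bad(!d$dvid %in% DVID_VOCAB,
      sprintf("dvid must be one of %s", paste(DVID_VOCAB, collapse = ", ")))
  bad(d$time < 0 | !is.finite(d$time), "time must be finite and >= 0")
  bad(d$evid == 1 & (is.na(d$amt) | d$amt <= 0),
      "dose record must carry a positive amt")
  bad(d$evid == 1 & d$mdv != 1, "dose record must have mdv = 1")
  bad(d$evid == 1 & !is.na(d$dv), "dose record must have missing dv")
  bad(d$evid == 0 & d$mdv == 0 & is.na(d$dv),
      "observation with mdv = 0 must carry a dv")
  bad(d$blq == 1 & is.na(d$lloq), "blq = 1 requires an lloq")
  bad(d$blq == 1 & d$mdv != 0, "blq record must be an observation (mdv = 0)")
  bad(!is.finite(d$wt) | d$wt <= 0, "wt must be > 0")
  for (s in split(seq_len(nrow(d)), d$id)) {
    if (is.unsorted(d$time[s])) {
      stop(sprintf("dataset: times not sorted within subject '%s'", d$id[s[1]]))
    }
  }
  if (!inherits(d, "pkpd_dataset")) class(d) <- c("pkpd_dataset", class(d))
  d
}

#' Read / write a dataset in NONMEM-convention CSV
#'
#' Column header `ID, TIME, EVID, AMT, RATE, DV, DVID, MDV, BLQ, LLOQ, WT,
#' SPECIES`; missing numeric fields are encoded as `"."`.  Reading validates
#' every dataset invariant with row-numbered error messages; writing is the
#' exact inverse so `write_dataset(read_dataset(f))` round-trips.
#'
#' @param path file path.
#' @return `read_dataset`: a validated `pkpd_dataset` data.frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(DATASET_COLS, names(raw))
  if (length(missing_cols)) {
    stop("dataset file missing columns: ", paste(missing_cols, collapse = ", "))
  }
  num <- function(col) {
    x <- raw[[col]]
    x[x == "."] <- NA_character_
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad)) {
      stop(sprintf("dataset line %d, column %s: non-numeric value '%s'",
                   which(bad)[1] + 1L, toupper(col), x[which(bad)[1]]))
    }
    as.numeric(x)
  }
  d <- data.frame(
    id = raw$id, time = num("time"), evid = as.integer(num("evid")),
    amt = num("amt"), rate = num("rate"), dv = num("dv"), dvid = raw$dvid,
    mdv = as.integer(num("mdv")), blq = as.integer(num("blq")),
    lloq = num("lloq"), wt = num("wt"), species = raw$species
  )
  validate_dataset(d)
}

#' @rdname read_dataset
#' @param dataset a `pkpd_dataset` (or conforming data.frame).
#' @export
write_dataset <- function(dataset, path) {
  d <- validate_dataset(dataset)
  out <- data.frame(
    ID = d$id, TIME = fmt_num(d$time), EVID = d$evid,
    AMT = fmt_num(d$amt), RATE = fmt_num(d$rate), DV = fmt_num(d$dv),
    DVID = d$dvid, MDV = d$mdv, BLQ = d$blq, LLOQ = fmt_num(d$lloq),
    WT = fmt_num(d$wt), SPECIES = d$species
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "." else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' @export
print.pkpd_dataset <- function(x, ...) {
  nobs <- sum(x$evid == 0)
  cat(sprintf(
    "PK/PD dataset: %d subjects, %d observations (%d BLQ), %d dose records\n",
    length(unique(x$id)), nobs, sum(x$blq == 1), sum(x$evid == 1)))
  cat("observables:", paste(sort(unique(x$dvid[x$evid == 0])), collapse = ", "),
      "\n")
  NextMethod()
}
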