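## On-disk formats.  The character matrix CSV stores raw (unlogged)
## values so files stay checkable against published measurements; the
## natural-log transform of the three histometric predictors is applied in
## memory at read time.  All CSVs: comma-separated, UTF-8, header row,
## empty field = missing.

RAW_COLS <- c("osteo_volume", "can_harmean", "can_min",
              "rbc_width", "rbc_area", "rbc_length")

## deterministic, full-precision CSV writer (byte-identical reruns)
.write_csv <- function(df, path) {
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", sprintf("%.15g", x))
    else ifelse(is.na(x), "", as.character(x))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a character matrix CSV into a trait table
#'
#' Expects columns `taxon, status, osteo_volume, can_harmean, can_min,
#' rbc_width, rbc_area, rbc_length` with raw (unlogged) values; empty
#' fields are missing.  The three histometric predictors are natural-log
#' transformed on read.  Row-level invariants are enforced: predictors
#' present and positive everywhere, fossil rows must have all responses
#' missing, extant rows at least one response present.
#'
#' @param path CSV file path.
#' @param quiet Suppress the partition-size message?
#' @return A trait-table data frame (columns `taxon`, `status`,
#'   `lnOsteo_volume`, `lnCan_harmean`, `lnCan_min`, `RBC_width`,
#'   `RBC_area`, `RBC_length`).
#' @export
read_character_matrix <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  required <- c("taxon", "status", RAW_COLS)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- function(col) {
    x <- raw[[col]]
    x[x == ""] <- NA
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad))
      stop("non-numeric value in column '", col, "', row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    as.numeric(x)
  }
  taxon <- trimws(raw$taxon)
  status <- trimws(raw$status)
  if (anyDuplicated(taxon))
    stop("duplicate taxon name(s): ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "),
         call. = FALSE)
  bad_status <- !status %in% c("extant", "fossil")
  if (any(bad_status))
    stop("status must be 'extant' or 'fossil'; bad row(s) ",
         paste(which(bad_status), collapse = ", "), call. = FALSE)
  vals <- lapply(RAW_COLS, num)
  names(vals) <- RAW_COLS
  for (col in c("osteo_volume", "can_harmean", "can_min")) {
    bad <- is.na(vals[[col]]) | vals[[col]] <= 0
    if (any(bad))
      stop("predictor '", col, "' must be present and > 0; bad row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
  }
  resp <- cbind(vals$rbc_width, vals$rbc_area, vals$rbc_length)
  has_resp <- rowSums(!is.na(resp)) > 0
  bad_fossil <- status == "fossil" & has_resp
  if (any(bad_fossil))
    stop("fossil row(s) carry a response value: row(s) ",
         paste(which(bad_fossil), collapse = ", "), call. = FALSE)
  bad_extant <- status == "extant" & !has_resp
  if (any(bad_extant))
    stop("extant row(s) have no response value: row(s) ",
         paste(which(bad_extant), collapse = ", "), call. = FALSE)
  neg <- !is.na(resp) & resp <= 0
  if (any(neg))
    stop("response values must be > 0; bad row(s) ",
         paste(which(rowSums(neg) > 0), collapse = ", "), call. = FALSE)
  if (!quiet)
    message(sum(status == "extant"), " extant + ",
            sum(status == "fossil"), " fossil taxa read from ", path)
  data.frame(
    taxon = taxon, status = status,
    lnOsteo_volume = log(vals$osteo_volume),
    lnCan_harmean = log(vals$can_harmean),
    lnCan_min = log(vals$can_min),
    RBC_width = vals$rbc_width,
    RBC_area = vals$rbc_area,
    RBC_length = vals$rbc_length,
    stringsAsFactors = FALSE
  )
}

#' Write a trait table as a raw character matrix CSV
#'
#' Inverse of [read_character_matrix()]: ln predictors are exponentiated
#' back to raw values.
#'
#' @param table A trait-table data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(table, path) {
  out <- data.frame(
    taxon = table$taxon,
    status = table$status,
    osteo_volume = exp(table$lnOsteo_volume),
    can_harmean = exp(table$lnCan_harmean),
    can_min = exp(table$lnCan_min),
    rbc_width = table$RBC_width,
    rbc_area = table$RBC_area,
    rbc_length = table$RBC_length,
    stringsAsFactors = FALSE
  )
  .write_csv(out, path)
}

#' Serialize a PEM basis to JSON
#'
#' Full-precision JSON bundle (matrices column-major with dimensions) so a
#' basis can be rebuilt by the CLI without re-reading the tree.
#'
#' @param basis A [build_pem()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pem_basis <- function(basis, path) {
  stopifnot(inherits(basis, "pem_basis"))
  mat <- function(m) list(dim = dim(m), data = as.numeric(m))
  obj <- list(
    tips = basis$tips,
    U = mat(basis$U), V = mat(basis$V),
    d = basis$d, means = basis$means,
    weighting = unclass(basis$weighting), rel_tol = basis$rel_tol,
    newick = write_newick(basis$influence$tree)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PEM basis written by [write_pem_basis()]
#'
#' @param path JSON path.
#' @return A `pem_basis` object.
#' @export
read_pem_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tree <- parse_newick(obj$newick)
  infl <- influence_matrix(tree)
  mat <- function(m) matrix(m$data, m$dim[1L], m$dim[2L])
  U <- mat(obj$U); V <- mat(obj$V)
  rownames(U) <- obj$tips
  colnames(U) <- colnames(V) <- sprintf("V_%d", seq_len(ncol(U)))
  structure(
    list(U = U, d = obj$d, V = V,
         means = stats::setNames(obj$means, colnames(infl$I)),
         weighting = structure(as.list(obj$weighting),
                               class = "edge_weighting"),
         tips = obj$tips, influence = infl, rel_tol = obj$rel_tol),
    class = "pem_basis"
  )
}
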