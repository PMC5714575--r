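#' Read DVHs from a plain-text exchange file
#'
#' Two dialects are accepted:
#'
#' * `"exchange"`: comment lines start with `#`; each structure block begins
#'   with a header line
#'   `structure=<label> kind=<cumulative|differential> dose_unit=Gy volume_unit=fraction`
#'   followed by two whitespace- or comma-separated columns (dose, volume);
#'   blocks are separated by blank lines.
#' * `"csv"`: strict CSV with header `structure,kind,dose_gy,volume`, one row
#'   per bin, structures grouped by label in file order.
#'
#' `dialect = "auto"` sniffs the first non-comment line. All type invariants
#' are validated on read; a malformed header is reported with its line number
#' and a non-monotone cumulative curve with its structure label.
#'
#' @param source path to a file, or a connection.
#' @param dialect `"auto"`, `"exchange"` or `"csv"`.
#' @return A list of [dvh] objects in file order.
#' @seealso [write_dvh()]
#' @export
read_dvh <- function(source, dialect = c("auto", "exchange", "csv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(source)
  if (dialect == "auto") {
    first <- grep("^\\s*(#|$)", lines, invert = TRUE, value = TRUE)
    if (length(first) == 0L) stop("no content in DVH source", call. = FALSE)
    dialect <- if (grepl("^\\s*structure\\s*,\\s*kind\\s*,\\s*dose_gy\\s*,\\s*volume\\s*$",
                         first[1L])) "csv" else "exchange"
  }
  if (dialect == "csv") read_dvh_csv(lines) else read_dvh_exchange(lines)
}

read_dvh_exchange <- function(lines) {
  keep <- !grepl("^\\s*#", lines)
  idx <- which(keep)
  lines <- lines[keep]
  blank <- grepl("^\\s*$", lines)
  block_id <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1L]))
  block_id[blank] <- NA
  out <- list()
  for (b in unique(stats::na.omit(block_id))) {
    sel <- which(!is.na(block_id) & block_id == b)
    hdr_line <- lines[sel[1L]]
    hdr_no <- idx[sel[1L]]
    toks <- strsplit(trimws(hdr_line), "\\s+")[[1L]]
    kv <- regmatches(toks, regexec("^([A-Za-z_]+)=(.+)$", toks))
    if (any(lengths(kv) != 3L))
      stop("malformed DVH header at line ", hdr_no, ": '", hdr_line, "'",
           call. = FALSE)
    keys <- vapply(kv, `[`, "", 2L)
    vals <- vapply(kv, `[`, "", 3L)
    names(vals) <- keys
    for (need in c("structure", "kind")) {
      if (!need %in% keys)
        stop("DVH header at line ", hdr_no, " lacks '", need, "='",
             call. = FALSE)
    }
    if (!vals[["kind"]] %in% c("cumulative", "differential"))
      stop("DVH header at line ", hdr_no, ": kind must be ",
           "'cumulative' or 'differential'", call. = FALSE)
    if ("dose_unit" %in% keys && vals[["dose_unit"]] != "Gy")
      stop("DVH header at line ", hdr_no, ": only dose_unit=Gy is supported",
           call. = FALSE)
    if ("volume_unit" %in% keys && vals[["volume_unit"]] != "fraction")
      stop("DVH header at line ", hdr_no,
           ": only volume_unit=fraction is supported", call. = FALSE)
    body <- lines[sel[-1L]]
    if (length(body) == 0L)
      stop("DVH block '", vals[["structure"]], "' (line ", hdr_no,
           ") has no data rows", call. = FALSE)
    fields <- strsplit(trimws(body), "[,[:space:]]+")
    if (any(lengths(fields) != 2L))
      stop("DVH block '", vals[["structure"]],
           "': each data row needs exactly two columns (dose, volume)",
           call. = FALSE)
    m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 2L, byrow = TRUE)
    if (anyNA(m))
      stop("DVH block '", vals[["structure"]], "': non-numeric data row",
           call. = FALSE)
    out[[length(out) + 1L]] <- dvh(m[, 1L], m[, 2L], kind = vals[["kind"]],
                                   structure = vals[["structure"]])
  }
  if (length(out) == 0L) stop("no DVH blocks found", call. = FALSE)
  out
}

read_dvh_csv <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)]
  df <- utils::read.csv(text = lines, stringsAsFactors = FALSE,
                        strip.white = TRUE)
  need <- c("structure", "kind", "dose_gy", "volume")
  if (!identical(names(df), need))
    stop("CSV DVH dialect requires header exactly '",
         paste(need, collapse = ","), "'", call. = FALSE)
  labs <- unique(df$structure)
  lapply(labs, function(lb) {
    rows <- df[df$structure == lb, ]
    kind <- unique(rows$kind)
    if (length(kind) != 1L)
      stop("structure '", lb, "' mixes cumulative and differential rows",
           call. = FALSE)
    dvh(rows$dose_gy, rows$volume, kind = kind, structure = lb)
  })
}

#' Write DVHs to the plain-text exchange format
#'
#' @param dvhs a [dvh] or list of them.
#' @param path output file path.
#' @param dialect `"exchange"` or `"csv"` (see [read_dvh()]).
#' @param digits significant digits for doses/volumes (default 12; round-trips
#'   doubles through [read_dvh()] to well below modelling tolerances).
#' @return `path`, invisibly.
#' @export
write_dvh <- function(dvhs, path, dialect = c("exchange", "csv"), digits = 12) {
  dialect <- match.arg(dialect)
  if (is_dvh(dvhs)) dvhs <- list(dvhs)
  stopifnot(all(vapply(dvhs, is_dvh, TRUE)))
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  if (dialect == "exchange") {
    blocks <- vapply(dvhs, function(d) {
      paste(c(sprintf("structure=%s kind=%s dose_unit=Gy volume_unit=fraction",
                      d$structure, d$kind),
              paste(fmt(d$dose), fmt(d$volume))),
            collapse = "\n")
    }, "")
    writeLines(paste(blocks, collapse = "\n\n"), path)
  } else {
    rows <- do.call(rbind, lapply(dvhs, function(d) {
      data.frame(structure = d$structure, kind = d$kind,
                 dose_gy = fmt(d$dose), volume = fmt(d$volume))
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
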