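# On-disk formats.
#
# All tab-separated files carry a single header line beginning with "#";
# site lists are 1-based and strand-explicit (the DARNED/RADAR convention).
# BED is used only for region exchange and is 0-based half-open, converted
# exactly at the boundary.

# -- generic "#"-headered TSV ------------------------------------------------

#' Read / write a tab-separated table with a "#"-prefixed header line
#'
#' The package's generic tabular format: one header line starting with
#' `#`, tab-separated body.  `write_hashed_tsv` serializes double
#' columns at full precision by default so round-trips are exact.
#'
#' @param path File path.
#' @param dt A data.frame/data.table.
#' @param full_precision Serialize doubles with `%.17g`.
#' @return `read_hashed_tsv` returns a data.table (first column read as
#'   character).
#' @export
read_hashed_tsv <- function(path) {
  if (!file.exists(path)) stop_rddkit("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    return(data.table::data.table())
  }
  if (!startsWith(first, "#"))
    stop_rddkit("expected a '#'-prefixed header line in ", path)
  header <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  empty <- data.table::as.data.table(
    stats::setNames(rep(list(character(0)), length(header)), header))
  n_lines <- length(readLines(path))
  if (n_lines <= 1L) return(empty)
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = FALSE,
                          colClasses = list(character = 1L), fill = TRUE)
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) != length(header))
    stop_rddkit("column count mismatch in ", path)
  data.table::setnames(dt, header)
  dt
}

#' @rdname read_hashed_tsv
#' @export
write_hashed_tsv <- function(dt, path, full_precision = TRUE) {
  dt <- data.table::as.data.table(dt)
  out <- data.table::copy(dt)
  if (full_precision) {
    for (j in names(out)) {
      if (is.double(out[[j]])) data.table::set(out, j = j, value = format_full(out[[j]]))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(out), collapse = "\t")), con)
  if (nrow(out))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# -- editing-site databases --------------------------------------------------

#' Read a known-editing-site table (DARNED/RADAR-style TSV)
#'
#' The file must have a header naming at least `chrom`, `pos` (or
#' `position`), `strand` and `type` columns; an optional `alt` column gives
#' an explicit variant allele.  Types are `"A-to-I"` or `"C-to-U"`.
#' Duplicate `(chrom,pos,strand)` rows are collapsed with a warning.
#'
#' @param path Path to the TSV file.
#' @param source_tag Free-text provenance label stored on the result.
#' @return An `editing_db` object (a data.table with columns
#'   `chrom,pos,strand,type[,alt]` and attributes `source_tag`,
#'   `n_duplicates`).
#' @export
read_editing_db <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop_rddkit("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop_rddkit("empty editing DB file (no header): ", path)
  hline <- sub("^#", "", lines[[1L]])
  header <- strsplit(hline, "\t", fixed = TRUE)[[1]]
  header[header == "position"] <- "pos"
  need <- c("chrom", "pos", "strand", "type")
  if (!all(need %in% header))
    stop_rddkit("editing DB header must name chrom, pos/position, strand, type")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  bad_len <- which(lengths(rows) != length(header))
  if (length(bad_len))
    stop_rddkit("malformed row (wrong field count) at line ", bad_len[1L] + 1L)
  m <- do.call(rbind, rows)
  dt <- if (length(body)) {
    data.table::as.data.table(stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), header))
  } else {
    data.table::as.data.table(stats::setNames(rep(list(character(0)), length(header)), header))
  }
  pos_num <- suppressWarnings(as.numeric(dt$pos))
  bad <- which(is.na(pos_num) | pos_num != floor(pos_num) | pos_num < 1)
  if (length(bad))
    stop_rddkit("non-integer or invalid position at line ", bad[1L] + 1L)
  dt[, "pos" := as.integer(pos_num)]
  bad <- which(!(dt$strand %in% c("+", "-")))
  if (length(bad))
    stop_rddkit("malformed strand '", dt$strand[bad[1L]], "' at line ", bad[1L] + 1L)
  bad <- which(!(dt$type %in% c("A-to-I", "C-to-U")))
  if (length(bad))
    stop_rddkit("unknown edit type '", dt$type[bad[1L]], "' at line ", bad[1L] + 1L)
  n0 <- nrow(dt)
  dt <- unique(dt, by = c("chrom", "pos", "strand"))
  ndup <- n0 - nrow(dt)
  if (ndup > 0L)
    warning(ndup, " duplicate (chrom,pos,strand) entr",
            if (ndup == 1L) "y" else "ies", " collapsed", call. = FALSE)
  keep <- intersect(c("chrom", "pos", "strand", "type", "alt"), names(dt))
  dt <- dt[, keep, with = FALSE]
  data.table::setkeyv(dt, c("chrom", "pos", "strand"))
  structure(dt, source_tag = source_tag, n_duplicates = ndup,
            class = c("editing_db", class(dt)))
}

#' Write an editing-site table
#' @param db An `editing_db` (or site data.frame with the same columns).
#' @param path Output path.
#' @export
write_editing_db <- function(db, path) {
  write_hashed_tsv(data.table::as.data.table(db), path, full_precision = FALSE)
}

#' Consensus (intersection) of two editing-site databases
#'
#' Sites present in both databases by `(chrom,pos,strand)`; the edit type
#' annotation is taken from the first database.
#'
#' @param dbA,dbB `editing_db` objects.
#' @return An `editing_db` with `source_tag = "consensus"`.
#' @export
consensus_db <- function(dbA, dbB) {
  a <- data.table::as.data.table(dbA)
  b <- data.table::as.data.table(dbB)
  check_site_cols(a, c("chrom", "pos", "strand", "type"))
  check_site_cols(b, c("chrom", "pos", "strand", "type"))
  out <- a[b[, c("chrom", "pos", "strand"), with = FALSE],
           on = c("chrom", "pos", "strand"), nomatch = NULL]
  out <- unique(out, by = c("chrom", "pos", "strand"))
  data.table::setkeyv(out, c("chrom", "pos", "strand"))
  structure(out, source_tag = "consensus", n_duplicates = 0L,
            class = c("editing_db", class(out)))
}

# -- candidate tables --------------------------------------------------------

candidate_cols <- function() {
  c("chrom", "pos", "ref", "alt", "n_ref", "n_alt", rdd_feature_names())
}

#' Write / read a candidate table
#'
#' The candidate table is the pipeline's canonical tabular interchange:
#' one row per `(chrom,pos)` with forward-strand `ref`/`alt`, supporting
#' counts and the 15 attribute columns.  Floats are serialized at full
#' precision so `read_candidates(write_candidates(x)) == x` field for field.
#'
#' @param table A candidate table (see [call_candidates()]).
#' @param path File path.
#' @return `read_candidates` returns the table with its `provenance`
#'   attribute restored.
#' @export
write_candidates <- function(table, path) {
  dt <- data.table::as.data.table(table)
  check_site_cols(dt, candidate_cols())
  prov <- attr(table, "provenance")
  con <- file(path, "w")
  writeLines(paste0("##provenance=", if (is.null(prov)) "" else prov), con)
  close(con)
  tmp <- tempfile()
  write_hashed_tsv(dt[, candidate_cols(), with = FALSE], tmp)
  file.append(path, tmp)
  unlink(tmp)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop_rddkit("file not found: ", path)
  lines <- readLines(path, n = 2L)
  prov <- NULL
  skip <- 0L
  if (length(lines) && startsWith(lines[[1L]], "##provenance=")) {
    prov <- sub("^##provenance=", "", lines[[1L]])
    skip <- 1L
  }
  tmp <- tempfile()
  writeLines(readLines(path)[-seq_len(skip)], tmp)
  dt <- read_hashed_tsv(tmp)
  unlink(tmp)
  miss <- setdiff(candidate_cols(), names(dt))
  if (length(miss))
    stop_rddkit("candidate table schema error: missing column(s) ",
                paste(miss, collapse = ", "))
  if (nrow(dt)) {
    int_cols <- c("pos", "n_ref", "n_alt")
    for (j in int_cols) data.table::set(dt, j = j, value = as.integer(dt[[j]]))
    for (j in setdiff(rdd_feature_names(), "ReadDepth"))
      data.table::set(dt, j = j, value = as.numeric(dt[[j]]))
    data.table::set(dt, j = "ReadDepth", value = as.numeric(dt$ReadDepth))
  } else {
    dt <- empty_candidate_table()
  }
  data.table::setkeyv(dt, c("chrom", "pos"))
  structure(dt, provenance = prov,
            class = c("candidate_table", class(dt)))
}

empty_candidate_table <- function() {
  cols <- candidate_cols()
  proto <- c(list(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), n_ref = integer(0), n_alt = integer(0)),
             stats::setNames(rep(list(numeric(0)), 15L), rdd_feature_names()))
  data.table::as.data.table(proto[cols])
}

# -- BED regions -------------------------------------------------------------

#' Read / write BED region files (0-based half-open on disk)
#'
#' Regions are merged (overlaps and bookended intervals collapsed) and
#' sorted on write, so write-then-read is the identity on merged, sorted
#' sets.  In memory regions are 1-based closed [GenomicRanges::GRanges].
#'
#' @param path BED file path.
#' @param regions A `GRanges` of 1-based closed intervals.
#' @return `read_bed_regions` returns a `GRanges`.
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) stop_rddkit("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(GenomicRanges::GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  start0 <- as.integer(vapply(parts, `[[`, "", 2L))
  end0 <- as.integer(vapply(parts, `[[`, "", 3L))
  if (any(is.na(start0)) || any(is.na(end0)))
    stop_rddkit("non-integer BED coordinates in ", path)
  if (any(start0 >= end0))
    stop_rddkit("BED interval with start >= end in ", path)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

#' @rdname read_bed_regions
#' @export
write_bed_regions <- function(regions, path) {
  regions <- GenomicRanges::reduce(GenomicRanges::sort(regions))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(regions)) {
    writeLines(paste(as.character(GenomicRanges::seqnames(regions)),
                     GenomicRanges::start(regions) - 1L,
                     GenomicRanges::end(regions), sep = "\t"), con)
  }
  invisible(path)
}

#' Convert a 1-based site list to single-base BED regions and back
#' @noRd
sites_to_regions <- function(sites, pad = 0L) {
  dt <- data.table::as.data.table(sites)
  check_site_cols(dt)
  if (!nrow(dt)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(dt$chrom,
                               IRanges::IRanges(pmax(1L, dt$pos - pad), dt$pos + pad))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

# -- generic site lists ------------------------------------------------------

#' Read / write a generic site list TSV
#'
#' Minimum columns `chrom`, `pos`; extra columns (e.g. `strand`, `label`)
#' are preserved.
#' @param path File path.
#' @param sites data.frame-like with at least `chrom`, `pos`.
#' @export
read_site_list <- function(path) {
  dt <- read_hashed_tsv(path)
  check_site_cols(dt)
  dt[, "pos" := as.integer(dt$pos)]
  data.table::setkeyv(dt, c("chrom", "pos"))
  dt[]
}

#' @rdname read_site_list
#' @export
write_site_list <- function(sites, path) {
  dt <- data.table::as.data.table(sites)
  check_site_cols(dt)
  write_hashed_tsv(dt, path, full_precision = FALSE)
}
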