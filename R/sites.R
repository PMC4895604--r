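# Genomic site conventions.
#
# A site is a strand-aware single-base coordinate: chrom, 1-based pos,
# strand in {+,-}, and (when known) ref/alt alleles given on the FORWARD
# genome strand.  Site tables are plain data.tables so they join cheaply;
# every table in the package uses these column names.

#' The 15 read-alignment-pattern attribute names, in canonical order
#'
#' Column order is fixed package-wide: models persist it, writers emit it,
#' and readers validate against it.
#'
#' @return Character vector of length 15.
#' @export
rdd_feature_names <- function() {
  c("ReadDepth", "VAF", "SGB", "FQ", "CallQual",
    "PV3", "MQB", "MQ0F", "MQ", "VDB",
    "RPB", "PV4", "PV2", "BQB", "PV1")
}

#' Attribute-to-category map of the six read-alignment-pattern categories
#'
#' @return Named character vector mapping each attribute to its category.
#' @export
rdd_feature_categories <- function() {
  c(ReadDepth = "Read depth",
    VAF = "Allele segregation", SGB = "Allele segregation",
    FQ = "Allele segregation", CallQual = "Allele segregation",
    PV3 = "Mapping quality", MQB = "Mapping quality",
    MQ0F = "Mapping quality", MQ = "Mapping quality",
    VDB = "Read position", RPB = "Read position", PV4 = "Read position",
    PV2 = "Base quality", BQB = "Base quality",
    PV1 = "Read strand")
}

#' Test forward-strand alleles against an edit type on an annotated strand
#'
#' RNA editing is read strand-relatively: A-to-I presents as A>G on a `+`
#' transcript and T>C on a `-` transcript; C-to-U as C>T on `+` and G>A on
#' `-`.  `ref`/`alt` are forward-genome alleles.
#'
#' @param ref,alt Forward-strand reference and variant alleles.
#' @param strand `"+"` or `"-"` (the annotated transcript strand).
#' @param type `"A-to-I"` or `"C-to-U"`.
#' @return Logical vector.
#' @export
edit_type_compatible <- function(ref, alt, strand, type) {
  stopifnot(length(ref) == length(alt))
  ok_ai <- (strand == "+" & ref == "A" & alt == "G") |
           (strand == "-" & ref == "T" & alt == "C")
  ok_cu <- (strand == "+" & ref == "C" & alt == "T") |
           (strand == "-" & ref == "G" & alt == "A")
  ifelse(type == "A-to-I", ok_ai, ifelse(type == "C-to-U", ok_cu, FALSE))
}

#' Substitution class of a site on its annotated strand
#'
#' One of the 12 ref>alt classes after projecting forward-strand alleles
#' onto the annotated strand (e.g. forward T>C on `-` is class `"A>G"`).
#'
#' @inheritParams edit_type_compatible
#' @return Character vector like `"A>G"`.
#' @export
substitution_class <- function(ref, alt, strand) {
  r <- ifelse(strand == "-", unname(complement_base(ref)), ref)
  a <- ifelse(strand == "-", unname(complement_base(alt)), alt)
  paste0(r, ">", a)
}

# validate the shared site columns; returns the table invisibly
check_site_cols <- function(x, cols = c("chrom", "pos")) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop_rddkit("missing required column(s): ", paste(miss, collapse = ", "))
  if ("pos" %in% cols && any(x$pos < 1L))
    stop_rddkit("positions must be 1-based (>= 1)")
  invisible(x)
}
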