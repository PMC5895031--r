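# Variant catalog handling: parsing, region classification, summaries.

REGION_CLASSES <- c("intronic", "utr", "coding_nonsynonymous",
                    "coding_synonymous")

#' Gene annotation for a single transcript
#'
#' Describes the exon/intron architecture of one protein-coding transcript
#' using 1-based closed genomic intervals on the coding strand. The CDS
#' length must be a whole number of codons; the encoded protein length is
#' `CDS/3 - 1` (the stop codon is not a residue).
#'
#' @param transcript_id Character scalar.
#' @param cds,utr5,utr3,introns Two-column matrices or data frames of
#'   `start`, `end` intervals (1-based, closed). `cds` is required; the
#'   others may be `NULL`.
#' @return An object of class `gene_annotation`.
#' @examples
#' gene_annotation("tx1", cds = cbind(101, 130 + 480))
#' @export
gene_annotation <- function(transcript_id, cds, utr5 = NULL, utr3 = NULL,
                            introns = NULL) {
  as_iv <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (ncol(x) != 2) stop_input("%s intervals need 2 columns", what)
    storage.mode(x) <- "double"
    colnames(x) <- c("start", "end")
    if (any(x[, 1] > x[, 2])) stop_input("inverted interval in %s", what)
    o <- order(x[, 1])
    x <- x[o, , drop = FALSE]
    if (nrow(x) > 1 && any(x[-1, 1] <= x[-nrow(x), 2]))
      stop_input("overlapping intervals in %s", what)
    x
  }
  cds <- as_iv(cds, "cds")
  if (is.null(cds) || nrow(cds) == 0) stop_input("cds intervals are required")
  cds_len <- sum(cds[, 2] - cds[, 1] + 1)
  if (cds_len %% 3 != 0)
    stop_input("CDS length (%d) is not a multiple of 3", cds_len)
  structure(list(
    transcript_id = transcript_id,
    cds_intervals = cds,
    utr5_intervals = as_iv(utr5, "utr5"),
    utr3_intervals = as_iv(utr3, "utr3"),
    intron_intervals = as_iv(introns, "introns"),
    cds_length = cds_len,
    protein_length = cds_len / 3 - 1
  ), class = "gene_annotation")
}

in_intervals <- function(pos, iv) {
  !is.null(iv) && any(pos >= iv[, 1] & pos <= iv[, 2])
}

# 1-based CDS coordinate of a genomic position (plus strand), or NA
cds_offset <- function(pos, cds) {
  off <- 0
  for (i in seq_len(nrow(cds))) {
    if (pos >= cds[i, 1] && pos <= cds[i, 2])
      return(off + pos - cds[i, 1] + 1)
    off <- off + cds[i, 2] - cds[i, 1] + 1
  }
  NA_real_
}

#' Read a variant table from TSV
#'
#' Reads a tab-separated catalog export into a variant table. Column names
#' are resolved through `dialect`, a named character vector mapping the
#' canonical fields (`id`, `position`, `region_class`, `protein_change`,
#' `maf`, `ref`, `alt`) to the file's column names. Rows violating the
#' record invariants are returned in a rejects table with a reason, never
#' silently dropped: catalog counts are audit quantities.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect Named character vector; entries for absent optional
#'   columns may be omitted. At least one of `position`/`region_class`
#'   must resolve to an existing column.
#' @return A list with elements `variants` (data frame: `id`, `position`,
#'   `region_class`, `protein_change`, `maf`, `ref`, `alt`) and `rejects`
#'   (data frame: `row`, `reason`).
#' @export
load_variant_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  default <- c(id = "id", position = "position", region_class = "region_class",
               protein_change = "protein_change", maf = "maf",
               ref = "ref", alt = "alt")
  map <- default
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0) stop_input("variant table is empty: %s", path)
  # explicitly remapped columns must exist
  if (!is.null(dialect)) {
    missing <- dialect[!dialect %in% names(raw)]
    if (length(missing))
      stop_input("configured column(s) not in file: %s",
                 paste(missing, collapse = ", "))
  }
  col <- function(field, as = identity) {
    nm <- map[[field]]
    if (!is.null(nm) && nm %in% names(raw)) as(raw[[nm]]) else
      rep(NA, nrow(raw))
  }
  if (!(map[["position"]] %in% names(raw)) &&
      !(map[["region_class"]] %in% names(raw)))
    stop_input("need a '%s' or '%s' column", map[["position"]],
               map[["region_class"]])
  v <- data.frame(
    id = as.character(col("id")),
    position = suppressWarnings(as.numeric(col("position"))),
    region_class = as.character(col("region_class")),
    protein_change = as.character(col("protein_change")),
    maf = suppressWarnings(as.numeric(col("maf"))),
    ref = as.character(col("ref")),
    alt = as.character(col("alt")),
    stringsAsFactors = FALSE)
  v$id[is.na(v$id) | v$id == ""] <- "n/a"
  v$region_class[!is.na(v$region_class) & v$region_class == ""] <- NA
  v$protein_change[!is.na(v$protein_change) & v$protein_change == ""] <- NA

  reason <- rep(NA_character_, nrow(v))
  no_locus <- is.na(v$position) & is.na(v$region_class)
  reason[no_locus] <- "neither position nor region_class present"
  bad_class <- !is.na(v$region_class) &
    !v$region_class %in% c(REGION_CLASSES, "utr5", "utr3")
  reason[is.na(reason) & bad_class] <- "unknown region_class"
  bad_maf <- !is.na(v$maf) & (v$maf < 0 | v$maf > 1)
  reason[is.na(reason) & bad_maf] <- "maf outside [0,1]"
  # protein_change present iff coding_nonsynonymous (when class known)
  pc_mismatch <- !is.na(v$region_class) &
    ((v$region_class == "coding_nonsynonymous") != !is.na(v$protein_change))
  reason[is.na(reason) & pc_mismatch] <-
    "protein_change presence inconsistent with region_class"

  keep <- is.na(reason)
  list(variants = v[keep, , drop = FALSE],
       rejects = data.frame(row = which(!keep), reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Classify the gene region of a variant
#'
#' Resolves a genomic position to `intronic`, `utr5`, `utr3`,
#' `coding_synonymous` or `coding_nonsynonymous` using the transcript
#' annotation. Coding positions are resolved by translating the reference
#' and alternate codon, so `ref` and `alt` alleles (coding-strand bases)
#' are required there.
#'
#' @param position 1-based genomic position.
#' @param annotation A [gene_annotation()].
#' @param cds_sequence Coding DNA sequence (character scalar, `ACGT`),
#'   length matching the annotated CDS.
#' @param ref,alt Single coding-strand bases; needed only for CDS positions.
#' @param pool_utr If `TRUE` (default), report `utr5`/`utr3` jointly as
#'   `"utr"`.
#' @return A region-class string.
#' @export
classify_region <- function(position, annotation, cds_sequence,
                            ref = NULL, alt = NULL, pool_utr = TRUE) {
  stopifnot(inherits(annotation, "gene_annotation"))
  cpos <- cds_offset(position, annotation$cds_intervals)
  if (!is.na(cpos)) {
    cds <- toupper(cds_sequence)
    if (nchar(cds) != annotation$cds_length)
      stop_input("cds_sequence length %d != annotated CDS length %d",
                 nchar(cds), annotation$cds_length)
    if (is.null(ref) || is.null(alt))
      stop_input("ref and alt alleles are required at CDS positions")
    codon_i <- ceiling(cpos / 3)
    codon <- substr(cds, 3 * codon_i - 2, 3 * codon_i)
    within <- cpos - 3 * (codon_i - 1)
    if (substr(codon, within, within) != toupper(ref))
      stop_input("ref allele %s does not match CDS base %s at CDS position %d",
                 ref, substr(codon, within, within), cpos)
    alt_codon <- codon
    substr(alt_codon, within, within) <- toupper(alt)
    same <- translate_codon(codon) == translate_codon(alt_codon)
    return(if (same) "coding_synonymous" else "coding_nonsynonymous")
  }
  if (in_intervals(position, annotation$intron_intervals)) return("intronic")
  if (in_intervals(position, annotation$utr5_intervals))
    return(if (pool_utr) "utr" else "utr5")
  if (in_intervals(position, annotation$utr3_intervals))
    return(if (pool_utr) "utr" else "utr3")
  stop_input("position %s falls outside all annotated intervals", position)
}

#' Summarize the region-class distribution of a catalog
#'
#' Counts variants per region class and computes one-decimal percentages
#' (half-up rounding, the convention used for printed catalog summaries).
#' 5' and 3' UTR variants are pooled under `utr`.
#'
#' @param variants Data frame with a `region_class` column (every row
#'   resolved), or a named vector/list of per-class counts.
#' @return Data frame with columns `class`, `count`, `percent`.
#' @examples
#' summarize_distribution(c(intronic = 674, utr = 52,
#'                          coding_nonsynonymous = 52,
#'                          coding_synonymous = 40))
#' @export
summarize_distribution <- function(variants) {
  if (is.data.frame(variants)) {
    if (nrow(variants) == 0) stop_input("empty variant list")
    cls <- variants$region_class
    if (any(is.na(cls))) stop_input("unresolved region_class present")
    cls[cls %in% c("utr5", "utr3")] <- "utr"
    counts <- table(factor(cls, levels = REGION_CLASSES))
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    counts <- unlist(variants)
    if (length(counts) == 0 || sum(counts) == 0)
      stop_input("empty variant list")
    nm <- names(counts)
    nm[nm %in% c("utr5", "utr3")] <- "utr"
    counts <- tapply(counts, nm, sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
    counts <- counts[order(match(names(counts), REGION_CLASSES))]
  }
  total <- sum(counts)
  data.frame(class = names(counts),
             count = unname(counts),
             percent = unname(round_half_up(100 * counts / total, 1)),
             stringsAsFactors = FALSE)
}

#' Parse protein-change tokens into residue substitutions
#'
#' Parses tokens of the form `<ref><position><alt>` with one-letter
#' amino-acid codes (e.g. `"A147T"`).
#'
#' @param x Character vector of tokens, or a variant data frame carrying
#'   `protein_change` (and optionally `id`) columns.
#' @param source_id Optional character vector of identifiers, recycled
#'   against the tokens.
#' @return Data frame with columns `ref_aa`, `position`, `alt_aa`,
#'   `source_id`.
#' @export
map_protein_variants <- function(x, source_id = NULL) {
  if (is.data.frame(x)) {
    keep <- !is.na(x$protein_change)
    source_id <- if ("id" %in% names(x)) x$id[keep] else NULL
    x <- x$protein_change[keep]
  }
  x <- as.character(x)
  if (is.null(source_id)) source_id <- x
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  parse1 <- function(tok, parts) {
    if (length(parts) != 4)
      stop_input("malformed protein-change token: '%s'", tok)
    ref <- toupper(parts[2]); alt <- toupper(parts[4])
    pos <- as.integer(parts[3])
    if (!ref %in% AA1 || !alt %in% AA1)
      stop_input("unknown amino-acid letter in token '%s'", tok)
    if (pos < 1) stop_input("position must be >= 1 in token '%s'", tok)
    if (ref == alt) stop_input("ref and alt identical in token '%s'", tok)
    list(ref, pos, alt)
  }
  parsed <- Map(parse1, x, m)
  data.frame(
    ref_aa = vapply(parsed, `[[`, "", 1),
    position = vapply(parsed, `[[`, 1L, 2),
    alt_aa = vapply(parsed, `[[`, "", 3),
    source_id = as.character(source_id),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Residues carrying more than one substitution
#'
#' @param pvs Data frame from [map_protein_variants()].
#' @return Named list: one element per residue position with >= 2 distinct
#'   substitutions, sorted ascending by position; each element is the
#'   subset of `pvs` at that position.
#' @export
multiallelic_residues <- function(pvs) {
  if (nrow(pvs) == 0) return(list())
  by_pos <- split(pvs, pvs$position)
  multi <- Filter(function(d) length(unique(d$alt_aa)) >= 2, by_pos)
  if (length(multi) == 0) return(list())
  multi[order(as.integer(names(multi)))]
}

#' Partition variants by minor allele frequency
#'
#' @param variants Variant data frame with a `maf` column.
#' @param min_maf Threshold in `[0,1]`; a record is retained iff
#'   `maf >= min_maf`.
#' @return List of data frames `retained`, `rare`, `unknown` (no MAF).
#' @export
filter_by_maf <- function(variants, min_maf = 0.003) {
  if (min_maf < 0 || min_maf > 1) stop_input("min_maf must be in [0,1]")
  maf <- variants$maf
  list(retained = variants[!is.na(maf) & maf >= min_maf, , drop = FALSE],
       rare = variants[!is.na(maf) & maf < min_maf, , drop = FALSE],
       unknown = variants[is.na(maf), , drop = FALSE])
}
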