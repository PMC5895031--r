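# Codon-usage relative adaptiveness, CDS profiles, synonymous-variant
# impact, and rare-codon cluster detection.

#' Embedded Homo sapiens codon-usage table
#'
#' Standard human codon-usage frequencies (occurrences per 1000 codons,
#' CUTG-style, aggregated over 93,487 GenBank CDSs), keyed by DNA codon.
#' Used as the default organism table for relative-adaptiveness analysis.
#'
#' @return Data frame with columns `codon`, `aa` (one-letter, `*` = stop)
#'   and `per1000`.
#' @export
human_codon_usage <- function() {
  per1000 <- c(
    TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9,
    CTT = 13.2, CTC = 19.6, CTA = 7.2, CTG = 39.6,
    ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
    GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1,
    TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG = 4.4,
    CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
    ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1,
    GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG = 7.4,
    TAT = 12.2, TAC = 15.3, TAA = 1.0, TAG = 0.8,
    CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
    AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
    GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
    TGT = 10.6, TGC = 12.6, TGA = 1.6, TGG = 13.2,
    CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4,
    AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
    GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5)
  data.frame(codon = names(per1000),
             aa = unname(GENETIC_CODE_DNA[names(per1000)]),
             per1000 = unname(per1000),
             stringsAsFactors = FALSE)
}

#' Read a codon-usage table from TSV
#'
#' Expects two columns, `codon` and `per1000` (occurrences per 1000
#' codons); all 64 codons must be present.
#'
#' @param path TSV path.
#' @return Data frame as [human_codon_usage()].
#' @export
read_codon_usage <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "per1000") %in% names(d)))
    stop_input("usage table needs 'codon' and 'per1000' columns")
  d$codon <- toupper(gsub("U", "T", toupper(d$codon)))
  if (!setequal(d$codon, names(GENETIC_CODE_DNA)) || nrow(d) != 64)
    stop_input("usage table must contain all 64 codons exactly once")
  d$aa <- unname(GENETIC_CODE_DNA[d$codon])
  d[, c("codon", "aa", "per1000")]
}

#' Relative adaptiveness of every codon
#'
#' Within each synonymous family the most frequent codon is set to 100%
#' and the others are scaled linearly by frequency. Values are kept at
#' full precision in `value`; `display` carries the integer-rounded form
#' used in reports. Ties for a family maximum give every tied codon 100
#' and set a tie flag. Stop codons are flagged and excluded from CDS
#' profiles downstream.
#'
#' @param usage Usage table from [human_codon_usage()] or
#'   [read_codon_usage()].
#' @return Data frame with columns `codon`, `aa`, `per1000`, `value`
#'   (exact percent), `display` (integer percent), `is_stop`, `tie`.
#' @examples
#' ad <- relative_adaptiveness(human_codon_usage())
#' ad[ad$codon %in% c("CTG", "CTA"), ]
#' @export
relative_adaptiveness <- function(usage = human_codon_usage()) {
  if (any(usage$per1000 < 0)) stop_input("negative codon frequency")
  fam_max <- tapply(usage$per1000, usage$aa, max)
  if (any(fam_max == 0))
    stop_input("amino-acid family with all-zero frequencies: %s",
               paste(names(fam_max)[fam_max == 0], collapse = ", "))
  mx <- fam_max[usage$aa]
  value <- 100 * usage$per1000 / as.numeric(mx)
  n_at_max <- tapply(usage$per1000 == as.numeric(mx), usage$aa, sum)
  out <- usage
  out$value <- value
  out$display <- as.integer(round_half_up(value, 0))
  out$is_stop <- usage$aa == "*"
  out$tie <- as.logical(n_at_max[usage$aa] > 1) & usage$per1000 == mx
  out
}

split_codons <- function(cds) {
  cds <- toupper(gsub("[[:space:]]", "", cds))
  if (nchar(cds) %% 3 != 0)
    stop_input("CDS length %d is not a multiple of 3", nchar(cds))
  if (grepl("[^ACGT]", cds))
    stop_input("CDS contains non-ACGT characters")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Per-position relative-adaptiveness profile of a CDS
#'
#' @param cds Coding DNA sequence (character scalar), in frame.
#' @param adapt Table from [relative_adaptiveness()].
#' @param drop_stop Exclude a trailing stop codon from the profile
#'   (default `TRUE`).
#' @return Data frame with `position` (1-based codon index), `codon`,
#'   `aa`, `value` (exact percent) and `display`.
#' @export
profile_cds <- function(cds, adapt = relative_adaptiveness(),
                        drop_stop = TRUE) {
  codons <- split_codons(cds)
  idx <- match(codons, adapt$codon)
  prof <- data.frame(position = seq_along(codons), codon = codons,
                     aa = adapt$aa[idx], value = adapt$value[idx],
                     display = adapt$display[idx],
                     stringsAsFactors = FALSE)
  if (drop_stop) prof <- prof[prof$aa != "*", , drop = FALSE]
  prof
}

#' Read a CDS from a FASTA file
#'
#' @param path FASTA path; the first sequence is used.
#' @return Uppercase DNA string.
#' @export
read_cds_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(seqs) == 0) stop_input("no sequences in %s", path)
  toupper(as.character(seqs[[1]]))
}

#' Codon-usage impact of a synonymous substitution
#'
#' @param cds Coding DNA sequence.
#' @param codon_position 1-based codon index of the substitution.
#' @param alt_codon Replacement codon; must encode the same amino acid.
#' @param adapt Table from [relative_adaptiveness()].
#' @return List with `wt_codon`, `alt_codon`, `wt` and `alt` adaptiveness
#'   (exact percent), `delta` (= alt - wt), and integer `wt_display`/
#'   `alt_display`.
#' @examples
#' \dontrun{ssnp_effect(cds, 113, "CTA")  # e.g. CTG -> CTA: 100 -> 18}
#' @export
ssnp_effect <- function(cds, codon_position, alt_codon,
                        adapt = relative_adaptiveness()) {
  codons <- split_codons(cds)
  if (codon_position < 1 || codon_position > length(codons))
    stop_input("codon_position %d out of range 1..%d", codon_position,
               length(codons))
  wt <- codons[codon_position]
  alt_codon <- toupper(alt_codon)
  if (!alt_codon %in% adapt$codon) stop_input("bad codon '%s'", alt_codon)
  if (translate_codon(wt) != translate_codon(alt_codon))
    stop_input("%s -> %s is not synonymous (%s vs %s)", wt, alt_codon,
               translate_codon(wt), translate_codon(alt_codon))
  wt_v <- adapt$value[adapt$codon == wt]
  alt_v <- adapt$value[adapt$codon == alt_codon]
  list(wt_codon = wt, alt_codon = alt_codon,
       wt = wt_v, alt = alt_v, delta = alt_v - wt_v,
       wt_display = adapt$display[adapt$codon == wt],
       alt_display = adapt$display[adapt$codon == alt_codon])
}

#' Detect rare-codon clusters in an adaptiveness profile
#'
#' Flags codon positions whose centered sliding-window mean adaptiveness
#' falls below `threshold`, then reports maximal runs of flagged positions
#' expanded by half a window on each side (clipped to the profile) and
#' merged where they overlap. With a uniform high-adaptiveness background
#' this recovers a planted low-adaptiveness block to within half a window.
#'
#' @param profile Data frame from [profile_cds()].
#' @param window Window width in codons (default 15).
#' @param threshold Mean-adaptiveness cutoff in percent (default 40).
#' @return Data frame with `start`, `end` (1-based codon positions,
#'   closed), `core_start`, `core_end` (the flagged run) and `mean_value`
#'   (mean profile value over start..end).
#' @export
detect_rare_clusters <- function(profile, window = 15, threshold = 40) {
  n <- nrow(profile)
  if (window < 1 || window > n)
    stop_input("window (%d) must be in 1..profile length (%d)", window, n)
  v <- profile$value
  pos <- profile$position
  half <- floor(window / 2)
  win_mean <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(v[lo:hi])
  }, 0)
  flagged <- win_mean < threshold
  if (!any(flagged))
    return(data.frame(start = integer(0), end = integer(0),
                      core_start = integer(0), core_end = integer(0),
                      mean_value = numeric(0)))
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  # expand by half a window, clip, then merge overlaps
  iv <- cbind(pmax(1, runs[, 1] - half), pmin(n, runs[, 2] + half))
  merged <- list(c(iv[1, ], runs[1, ]))
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    if (iv[i, 1] <= last[2] + 1) {
      last[2] <- max(last[2], iv[i, 2]); last[4] <- runs[i, 2]
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1]] <- c(iv[i, ], runs[i, ])
  }
  m <- do.call(rbind, merged)
  data.frame(start = pos[m[, 1]], end = pos[m[, 2]],
             core_start = pos[m[, 3]], core_end = pos[m[, 4]],
             mean_value = vapply(seq_len(nrow(m)), function(i)
               mean(v[m[i, 1]:m[i, 2]]), 0))
}
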