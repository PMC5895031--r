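# Consensus deleteriousness classification from an eight-predictor panel.
#
# Each predictor's published output (categorical label or numeric score) is
# binarized to damaging/benign under tool-specific rules, and a variant is
# called deleterious (D) when at least 5 of the 8 predictors vote damaging.

PREDICTOR_TOOLS <- c("provean", "sift", "polyphen2", "phdsnp", "snap2",
                     "snpsgo", "fathmm", "imutant3")

normalize_tool <- function(tool) {
  key <- gsub("[^a-z0-9]", "", tolower(tool))
  key[key == "imutant"] <- "imutant3"
  key[key == "polyphen"] <- "polyphen2"
  if (!all(key %in% PREDICTOR_TOOLS))
    stop_input("unknown predictor tool(s): %s",
               paste(tool[!key %in% PREDICTOR_TOOLS], collapse = ", "))
  key
}

normalize_category <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  # wording variants: "large decrease of stability" / "... in stability"
  x <- sub(" (of|in) stability$", "", x)
  x
}

#' Default predictor binarization rules
#'
#' Returns the rule set mapping each tool's raw output to a damaging/benign
#' call. Categorical labels are matched case-insensitively; numeric scores
#' use the tools' published thresholds: SIFT < 0.05 damaging; PolyPhen-2
#' probabilistic score > 0.85 damaging (the 0.15-0.85 "possibly damaging"
#' band and < 0.15 count as benign); SNPs&GO score strictly > 0.5 damaging;
#' I-Mutant DDG < -0.5 kcal/mol damaging (the -0.5..0.5 neutral band and
#' stabilizing changes are benign).
#'
#' PolyPhen-2 "possibly damaging" is deliberately a benign vote: it is the
#' only assignment consistent with the full published 52-row panel.
#'
#' @return Named list of per-tool rules (class `binarization_rules`).
#' @export
binarization_rules <- function() {
  cat_rule <- function(damaging, benign) list(damaging = damaging,
                                              benign = benign, num = NULL)
  rules <- list(
    provean = cat_rule("deleterious", "neutral"),
    sift = list(damaging = c("damaging", "deleterious"),
                benign = "tolerated",
                num = function(s) s < 0.05),
    polyphen2 = list(damaging = c("probably damaging", "most likely damaging"),
                     benign = c("possibly damaging", "benign"),
                     num = function(s) s > 0.85),
    phdsnp = cat_rule("disease", "neutral"),
    snap2 = cat_rule(c("effect", "non-neutral"), "neutral"),
    snpsgo = list(damaging = "disease", benign = "neutral",
                  num = function(s) s > 0.5),
    fathmm = cat_rule("damaging", "tolerated"),
    imutant3 = list(damaging = "large decrease",
                    benign = c("neutral", "large increase", "increase"),
                    num = function(ddg) ddg < -0.5))
  structure(rules, class = "binarization_rules")
}

#' Binarize one predictor call
#'
#' @param tool Tool identifier (one of PROVEAN, SIFT, PolyPhen2, PhD-SNP,
#'   SNAP2, SNPsGO, FATHMM, IMutant3; punctuation/case-insensitive).
#' @param raw Numeric score or categorical label as published.
#' @param rules Rule set from [binarization_rules()].
#' @return `"damaging"` or `"benign"`.
#' @examples
#' binarize_call("SIFT", 0.03)
#' binarize_call("PolyPhen2", "possibly damaging")
#' @export
binarize_call <- function(tool, raw, rules = binarization_rules()) {
  key <- normalize_tool(tool)
  rule <- rules[[key]]
  if (is.numeric(raw)) {
    if (is.null(rule$num))
      stop_input("tool %s has no numeric threshold rule", tool)
    return(if (rule$num(raw)) "damaging" else "benign")
  }
  cat <- normalize_category(raw)
  if (cat %in% rule$damaging) return("damaging")
  if (cat %in% rule$benign) return("benign")
  stop_input("tool %s: unrecognized category '%s'", tool, raw)
}

#' Consensus vote over a full predictor panel
#'
#' @param calls Named vector/list of exactly 8 binarized calls
#'   (`"damaging"`/`"benign"`), one per predictor tool.
#' @param id Optional variant identifier carried into the result.
#' @return List with `id`, `votes` (0-8 damaging count), `label`
#'   (`"D"` iff votes >= 5, else `"N"`) and the per-tool `calls`.
#' @export
consensus_classify <- function(calls, id = NA_character_) {
  calls <- unlist(calls)
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    stop_input("calls must be named by tool")
  keys <- normalize_tool(names(calls))
  if (anyDuplicated(keys)) stop_input("duplicated tool in panel")
  if (length(keys) != 8 || !setequal(keys, PREDICTOR_TOOLS))
    stop_input("panel must contain exactly one call per each of the 8 tools")
  if (!all(calls %in% c("damaging", "benign")))
    stop_input("calls must be 'damaging' or 'benign'")
  votes <- sum(calls == "damaging")
  list(id = id, votes = votes, label = if (votes >= 5) "D" else "N",
       calls = stats::setNames(unname(calls), keys))
}

resolve_tool_columns <- function(nms) {
  keys <- gsub("[^a-z0-9]", "", tolower(nms))
  keys[keys == "imutant"] <- "imutant3"
  keys[keys == "polyphen"] <- "polyphen2"
  keys[keys == "snpsgp"] <- "snpsgo"  # published header typo
  idx <- match(PREDICTOR_TOOLS, keys)
  if (any(is.na(idx)))
    stop_input("predictor column(s) not found: %s",
               paste(PREDICTOR_TOOLS[is.na(idx)], collapse = ", "))
  stats::setNames(nms[idx], PREDICTOR_TOOLS)
}

#' Classify a table of predictor panels
#'
#' Binarizes every row's eight predictor outputs, applies the consensus
#' vote, and — when the table carries published labels — emits a row-by-row
#' concordance report. Published labels are never overwritten; rows where
#' the re-derived label disagrees with the printed one are surfaced in the
#' report so transcription or rule discrepancies stay auditable.
#'
#' @param rows Data frame with an identifier column (`snp_id`/`id`), a
#'   `mutation` token column, one column per predictor tool and optionally
#'   a printed `consensus` label column (`N`/`D`).
#' @param rules Rule set from [binarization_rules()].
#' @return List with `results` (data frame: id, mutation, per-tool calls,
#'   `votes`, `label`) and `concordance` (`NULL` without printed labels;
#'   otherwise list of `n`, `n_match`, `mismatches` data frame).
#' @export
classify_table <- function(rows, rules = binarization_rules()) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop_input("empty predictor table")
  tool_cols <- resolve_tool_columns(names(rows))
  id_col <- intersect(c("snp_id", "id", "rsid"), names(rows))[1]
  ids <- if (!is.na(id_col)) as.character(rows[[id_col]]) else
    as.character(seq_len(nrow(rows)))
  mut <- if ("mutation" %in% names(rows)) as.character(rows$mutation) else
    rep(NA_character_, nrow(rows))

  calls <- sapply(PREDICTOR_TOOLS, function(tool) {
    vapply(rows[[tool_cols[[tool]]]], function(raw)
      binarize_call(tool, raw, rules), "", USE.NAMES = FALSE)
  })
  calls <- matrix(calls, nrow = nrow(rows),
                  dimnames = list(NULL, PREDICTOR_TOOLS))
  votes <- rowSums(calls == "damaging")
  res <- data.frame(id = ids, mutation = mut, as.data.frame(calls),
                    votes = as.integer(votes),
                    label = ifelse(votes >= 5, "D", "N"),
                    stringsAsFactors = FALSE)

  concordance <- NULL
  if ("consensus" %in% names(rows)) {
    printed <- toupper(trimws(as.character(rows$consensus)))
    res$printed_label <- printed
    match_row <- res$label == printed
    concordance <- list(
      n = nrow(res),
      n_match = sum(match_row),
      mismatches = res[!match_row,
                       c("id", "mutation", "votes", "label", "printed_label"),
                       drop = FALSE])
  }
  list(results = res, concordance = concordance)
}

#' Count deleterious variants inside residue ranges
#'
#' Counts consensus-deleterious variants whose substituted residue falls in
#' a set of 1-based closed residue intervals (for example transmembrane
#' domains). A variant hit by several overlapping ranges is counted once in
#' the total (union semantics).
#'
#' @param results Results data frame from [classify_table()] (needs
#'   `mutation` and `label`).
#' @param ranges Two-column matrix/data frame of `start`, `end` residue
#'   intervals.
#' @param use_printed Count by the printed label when present (default
#'   `FALSE`: re-derived label).
#' @return List with `per_range` (data frame start, end, count, mutations)
#'   and `total` (unique deleterious variants in the union).
#' @export
region_enrichment <- function(results, ranges, use_printed = FALSE) {
  ranges <- as.matrix(ranges)
  if (length(ranges) == 0)
    return(list(per_range = data.frame(start = numeric(0), end = numeric(0),
                                       count = integer(0)), total = 0L))
  if (ncol(ranges) != 2 || any(ranges[, 1] > ranges[, 2]))
    stop_input("ranges must be two columns with start <= end")
  label <- if (use_printed && "printed_label" %in% names(results))
    results$printed_label else results$label
  dset <- results[label == "D", , drop = FALSE]
  pos <- map_protein_variants(dset$mutation)$position
  per <- lapply(seq_len(nrow(ranges)), function(i) {
    hit <- pos >= ranges[i, 1] & pos <= ranges[i, 2]
    data.frame(start = ranges[i, 1], end = ranges[i, 2],
               count = sum(hit),
               mutations = paste(dset$mutation[hit], collapse = ","),
               stringsAsFactors = FALSE)
  })
  in_union <- Reduce(`|`, lapply(seq_len(nrow(ranges)), function(i)
    pos >= ranges[i, 1] & pos <= ranges[i, 2]))
  list(per_range = do.call(rbind, per), total = sum(in_union))
}

#' Deleterious variants at evolutionarily conserved residues
#'
#' Intersects the consensus-deleterious set with a per-residue conservation
#' track (grades 1 = variable to 9 = conserved).
#'
#' @param results Results data frame from [classify_table()].
#' @param track Integer vector of per-residue conservation grades in 1..9,
#'   length = protein length.
#' @param min_score Grade at or above which a residue counts as highly
#'   conserved (default 8).
#' @param use_printed Use printed labels when present.
#' @return List with `subset` (deleterious rows at conserved residues),
#'   `n_conserved`, and `n_deleterious`.
#' @export
conservation_overlay <- function(results, track, min_score = 8,
                                 use_printed = FALSE) {
  if (!all(track %in% 1:9))
    stop_input("conservation track values must be integers in 1..9")
  if (!(min_score %in% 1:9)) stop_input("min_score must be in 1..9")
  label <- if (use_printed && "printed_label" %in% names(results))
    results$printed_label else results$label
  dset <- results[label == "D", , drop = FALSE]
  pos <- map_protein_variants(dset$mutation)$position
  if (any(pos > length(track)))
    stop_input("conservation track shorter than variant positions")
  keep <- track[pos] >= min_score
  list(subset = dset[keep, , drop = FALSE],
       n_conserved = sum(keep),
       n_deleterious = nrow(dset))
}

#' Path to the packaged predictor-panel fixture
#'
#' The published 52-row missense-variant predictor panel for the 169-residue
#' translocator protein TSPO (eight tool calls and a printed consensus label
#' per variant), shipped as a plain TSV.
#'
#' @return File path.
#' @export
tspo_panel_path <- function() {
  system.file("extdata", "tspo_nssnp_predictions.tsv", package = "varstab",
              mustWork = TRUE)
}
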