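# Seeded synthetic-data generators. Every generator returns its inputs
# together with a ground-truth manifest, so downstream recovery tests can
# read the truth from the manifest alone.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Write a truth manifest as JSON
#'
#' @param truth Manifest list (as attached by the generators).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a class-labelled variant catalog
#'
#' Draws `n` variants with region classes sampled from `fractions` and,
#' for the non-synonymous class, protein-change tokens over a protein of
#' `protein_length` residues. `n_duplicate_positions` residue positions
#' are planted with two distinct substitutions each. MAFs are drawn mostly
#' rare (< 0.003) with an occasional common allele.
#'
#' @param n Number of variants.
#' @param fractions Named fractions over the four region classes
#'   (must sum to 1).
#' @param n_duplicate_positions Residues planted with two substitutions.
#' @param protein_length Protein length in residues (default 169).
#' @param seed Integer seed.
#' @return List with `variants` (data frame) and `truth` manifest
#'   (seed, fractions, planted class per row, duplicate positions).
#' @export
gen_variant_catalog <- function(n,
                                fractions = c(intronic = 0.824, utr = 0.064,
                                              coding_nonsynonymous = 0.064,
                                              coding_synonymous = 0.048),
                                n_duplicate_positions = 0,
                                protein_length = 169, seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_input("fractions must sum to 1")
  if (!setequal(names(fractions), REGION_CLASSES))
    stop_input("fractions must be named by the four region classes")
  with_seed(seed, {
    if (n == 0) {
      return(list(variants = data.frame(id = character(0),
                                        region_class = character(0),
                                        protein_change = character(0),
                                        maf = numeric(0)),
                  truth = list(seed = seed, n = 0,
                               fractions = as.list(fractions),
                               classes = character(0),
                               duplicate_positions = integer(0))))
    }
    cls <- sample(names(fractions), n, replace = TRUE, prob = fractions)
    ns_idx <- which(cls == "coding_nonsynonymous")
    n_dup <- min(n_duplicate_positions, floor(length(ns_idx) / 2))
    tokens <- rep(NA_character_, n)
    if (length(ns_idx) > 0) {
      n_pos_needed <- length(ns_idx) - n_dup
      positions <- sample(protein_length, n_pos_needed)
      dup_pos <- if (n_dup > 0) positions[seq_len(n_dup)] else integer(0)
      pos_per_var <- c(positions, dup_pos)[seq_along(ns_idx)]
      tok <- vapply(pos_per_var, function(p) {
        aas <- sample(AA1, 2)
        paste0(aas[1], p, aas[2])
      }, "")
      # planted duplicates: same position & ref, different alt
      if (n_dup > 0) for (j in seq_len(n_dup)) {
        first <- tok[match(dup_pos[j], pos_per_var)]
        ref <- substr(first, 1, 1)
        alt1 <- substr(first, nchar(first), nchar(first))
        alt2 <- sample(setdiff(AA1, c(ref, alt1)), 1)
        k <- length(pos_per_var) - n_dup + j
        tok[k] <- paste0(ref, dup_pos[j], alt2)
      }
      tokens[ns_idx] <- tok
      dup_out <- sort(dup_pos)
    } else dup_out <- integer(0)
    maf <- ifelse(stats::runif(n) < 0.95,
                  stats::runif(n, 0, 0.003), stats::runif(n, 0.003, 0.5))
    variants <- data.frame(
      id = sprintf("synth%05d", seq_len(n)),
      region_class = cls, protein_change = tokens, maf = maf,
      stringsAsFactors = FALSE)
    list(variants = variants,
         truth = list(seed = seed, n = n, fractions = as.list(fractions),
                      classes = cls, duplicate_positions = dup_out))
  })
}

DAMAGING_LABELS <- c(provean = "Deleterious", sift = "Damaging",
                     polyphen2 = "probably damaging", phdsnp = "Disease",
                     snap2 = "Effect", snpsgo = "Disease",
                     fathmm = "Damaging",
                     imutant3 = "Large decrease of stability")
BENIGN_LABELS <- list(provean = "Neutral", sift = "Tolerated",
                      polyphen2 = c("benign", "possibly damaging"),
                      phdsnp = "Neutral", snap2 = "Neutral",
                      snpsgo = "Neutral", fathmm = "Tolerated",
                      imutant3 = "Neutral")

#' Generate predictor panels with planted vote counts
#'
#' Each row's eight categorical predictor calls are drawn so that exactly
#' `votes[i]` of them are damaging; the truth label follows the consensus
#' rule (>= 5 damaging votes = D). Benign PolyPhen-2 calls are drawn from
#' both benign wordings ("benign", "possibly damaging") to exercise the
#' binarization.
#'
#' @param n Number of variants.
#' @param votes Integer vector (0-8) of planted damaging-vote counts,
#'   recycled to length `n`; default uniform over 0..8.
#' @param protein_length Protein length for mutation tokens.
#' @param seed Integer seed.
#' @return List with `panels` (data frame shaped like the packaged
#'   fixture, without a printed consensus column) and `truth`
#'   (votes and labels per row).
#' @export
gen_predictor_panels <- function(n, votes = NULL, protein_length = 169,
                                 seed = 1) {
  with_seed(seed, {
    votes <- if (is.null(votes)) sample(0:8, n, replace = TRUE) else
      rep_len(as.integer(votes), n)
    if (any(votes < 0 | votes > 8)) stop_input("votes must be in 0..8")
    rows <- lapply(seq_len(n), function(i) {
      dmg <- sample(PREDICTOR_TOOLS, votes[i])
      vapply(PREDICTOR_TOOLS, function(tool) {
        if (tool %in% dmg) DAMAGING_LABELS[[tool]] else {
          opts <- BENIGN_LABELS[[tool]]
          if (length(opts) > 1) sample(opts, 1) else opts
        }
      }, "")
    })
    calls <- do.call(rbind, rows)
    pos <- sample(protein_length, n, replace = TRUE)
    tok <- vapply(seq_len(n), function(i) {
      aas <- sample(AA1, 2); paste0(aas[1], pos[i], aas[2])
    }, "")
    panels <- data.frame(snp_id = sprintf("synth%05d", seq_len(n)),
                         mutation = tok, calls, stringsAsFactors = FALSE)
    list(panels = panels,
         truth = list(seed = seed, votes = votes,
                      labels = ifelse(votes >= 5, "D", "N")))
  })
}

#' Generate a CDS with planted rare-codon blocks
#'
#' Codons outside the planted blocks are family-maximal (relative
#' adaptiveness 100); codons inside a block are family-minimal codons of
#' amino acids with low minimal adaptiveness, so a windowed profile dips
#' well below typical cluster thresholds exactly over the blocks.
#'
#' @param n_codons Number of sense codons (default 169).
#' @param blocks List of `c(start, end)` codon intervals (1-based,
#'   closed) to plant as rare-codon blocks.
#' @param adapt Adaptiveness table (defaults to the embedded human table).
#' @param add_stop Append a stop codon (default `TRUE`).
#' @param seed Integer seed.
#' @return List with `cds` (DNA string) and `truth` (blocks, seed).
#' @export
gen_cds <- function(n_codons = 169, blocks = list(),
                    adapt = relative_adaptiveness(), add_stop = TRUE,
                    seed = 1) {
  with_seed(seed, {
    sense <- adapt[!adapt$is_stop, ]
    fam_max <- do.call(rbind, lapply(split(sense, sense$aa), function(d)
      d[which.max(d$value), ]))
    fam_min <- do.call(rbind, lapply(split(sense, sense$aa), function(d)
      d[which.min(d$value), ]))
    low_aa <- fam_min$aa[fam_min$value <= 30 & fam_min$aa != "*"]
    codons <- fam_max$codon[match(sample(fam_max$aa, n_codons, replace = TRUE),
                                  fam_max$aa)]
    for (b in blocks) {
      if (b[1] < 1 || b[2] > n_codons || b[1] > b[2])
        stop_input("bad block [%s, %s]", b[1], b[2])
      idx <- b[1]:b[2]
      aa <- sample(low_aa, length(idx), replace = TRUE)
      codons[idx] <- fam_min$codon[match(aa, fam_min$aa)]
    }
    codons[1] <- "ATG"
    cds <- paste0(paste(codons, collapse = ""), if (add_stop) "TGA" else "")
    list(cds = cds,
         truth = list(seed = seed, n_codons = n_codons,
                      blocks = lapply(blocks, as.integer)))
  })
}

#' Idealized helical reference structure
#'
#' A generated alpha-helical dummy chain (default 169 residues, the length
#' of the translocator protein analysed by the pipeline) providing
#' reference coordinates for trajectory synthesis without any structure
#' download. Geometry is an ideal helix (1.5 A rise and 100 degrees twist
#' per residue); with `backbone = TRUE`, N, CA, C and O atoms are placed
#' on phase-shifted helices of similar radius.
#'
#' @param n_res Number of residues (default 169).
#' @param backbone Include N, C, O in addition to CA (default `FALSE`).
#' @return List with `atoms` (data frame) and `coords` (`N x 3` matrix).
#' @export
helical_reference <- function(n_res = 169, backbone = FALSE) {
  rise <- 1.5; twist <- 100 * pi / 180
  place <- function(i, radius, phase, dz) {
    th <- (i - 1) * twist + phase
    c(radius * cos(th), radius * sin(th), (i - 1) * rise + dz)
  }
  specs <- if (backbone)
    list(N = c(1.6, -0.45, -0.6), CA = c(2.3, 0, 0),
         C = c(1.7, 0.5, 0.7), O = c(2.0, 0.9, 1.1))
  else list(CA = c(2.3, 0, 0))
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i)
    data.frame(elety = names(specs), resid = "ALA", resno = i,
               elesy = substr(names(specs), 1, 1),
               stringsAsFactors = FALSE)))
  coords <- do.call(rbind, lapply(seq_len(n_res), function(i)
    t(vapply(specs, function(s) place(i, s[1], s[2], s[3]), numeric(3)))))
  rownames(coords) <- NULL
  list(atoms = atoms, coords = coords)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a synthetic trajectory with known fluctuation amplitudes
#'
#' Frames are built as `rigid_motion(t) o (reference + noise)`, where the
#' noise is per-atom isotropic Gaussian with a per-residue per-coordinate
#' standard deviation `sigma`, and the rigid motion is an optional slow
#' global rotation plus translation drift. Superposition-based analytics
#' should recover `sigma * sqrt(3)` as RMSF irrespective of the rigid
#' motion.
#'
#' @param n_frames Number of frames.
#' @param sigma Per-coordinate fluctuation SD in Angstrom; scalar or
#'   per-residue vector.
#' @param reference Reference from [helical_reference()] (default CA-only,
#'   169 residues).
#' @param rigid_motion Apply a global rotation/translation schedule
#'   (default `TRUE`).
#' @param dt_ps Frame spacing in ps (default 25).
#' @param seed Integer seed.
#' @return List with `traj` (a [trajectory()]) and `truth`
#'   (per-residue sigma, expected RMSF `sigma * sqrt(3)`, schedule).
#' @export
gen_trajectory <- function(n_frames, sigma = 1, reference = NULL,
                           rigid_motion = TRUE, dt_ps = 25, seed = 1) {
  ref <- reference %||% helical_reference()
  n_res <- length(unique(ref$atoms$resno))
  sig_res <- rep_len(sigma, n_res)
  sig_atom <- sig_res[ref$atoms$resno]
  n_atoms <- nrow(ref$coords)
  with_seed(seed, {
    axis <- c(1, 2, 3)
    xyz <- matrix(NA_real_, n_frames, 3 * n_atoms)
    for (f in seq_len(n_frames)) {
      noise <- matrix(stats::rnorm(3 * n_atoms, sd = rep(sig_atom, each = 3)),
                      ncol = 3, byrow = TRUE)
      coords <- ref$coords + noise
      if (rigid_motion) {
        ang <- 2 * pi * (f - 1) / max(n_frames, 2)
        R <- rotation_matrix(axis, ang)
        shift <- c(10, -5, 3) * (f - 1) / max(n_frames - 1, 1)
        coords <- coords %*% t(R) + matrix(shift, n_atoms, 3, byrow = TRUE)
      }
      xyz[f, ] <- as.numeric(t(coords))
    }
    traj <- trajectory(ref$atoms, xyz, dt_ps = dt_ps)
    list(traj = traj,
         truth = list(seed = seed, n_frames = n_frames,
                      sigma = sig_res, expected_rmsf = sig_res * sqrt(3),
                      rigid_motion = rigid_motion, dt_ps = dt_ps))
  })
}

#' Generate a cycloheximide-chase densitometry table
#'
#' Replicated first-order decay with multiplicative lognormal noise:
#' `target = loading * 100 * exp(-t * ln 2 / half_life) * noise`, with the
#' loading control itself drawn lognormally around 1.
#'
#' @param half_life True half-life in hours (`Inf` = stable protein).
#' @param times Chase time points in hours (must include 0).
#' @param n_replicates Number of independent series (default 3).
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.10).
#' @param seed Integer seed.
#' @return List with `chase` (data frame: replicate, time_h,
#'   target_density, loading_density) and `truth`.
#' @export
gen_chase <- function(half_life = 30, times = c(0, 4, 8, 16, 24),
                      n_replicates = 3, cv = 0.10, seed = 1) {
  if (!0 %in% times) stop_input("times must include 0")
  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    rows <- expand.grid(replicate = sprintf("rep%d", seq_len(n_replicates)),
                        time_h = sort(times), stringsAsFactors = FALSE)
    k <- if (is.finite(half_life)) log(2) / half_life else 0
    loading <- stats::rlnorm(nrow(rows), 0, 0.2)
    noise <- stats::rlnorm(nrow(rows), -sdlog^2 / 2, sdlog)
    rows$loading_density <- loading
    rows$target_density <- loading * 100 * exp(-k * rows$time_h) * noise
    list(chase = rows[order(rows$replicate, rows$time_h), ],
         truth = list(seed = seed, half_life = half_life, k = k,
                      times = sort(times), n_replicates = n_replicates,
                      cv = cv))
  })
}

#' Synthetic gene model with known per-position region classes
#'
#' Builds a single-transcript gene (5' UTR, CDS exons, introns, 3' UTR)
#' with a random in-frame CDS, and a table of genomic positions with
#' ground-truth region classes, including coding positions with ref/alt
#' alleles whose synonymy is decided by codon translation.
#'
#' @param n_codons Sense codons in the CDS (default 60; a stop codon is
#'   appended).
#' @param seed Integer seed.
#' @return List with `annotation` ([gene_annotation()]), `cds_sequence`,
#'   and `positions` (data frame: position, ref, alt, truth_class).
#' @export
gen_gene_model <- function(n_codons = 60, seed = 1) {
  with_seed(seed, {
    cds_len <- 3 * (n_codons + 1)
    # layout: utr5 [1,100]; exon1 [101,100+e1]; intron [.. +200]; exon2; utr3
    e1 <- (floor(cds_len / 2) %/% 3) * 3  # keep both exons in frame-friendly sizes
    e2 <- cds_len - e1
    utr5 <- c(1, 100)
    ex1 <- c(101, 100 + e1)
    intr <- c(ex1[2] + 1, ex1[2] + 200)
    ex2 <- c(intr[2] + 1, intr[2] + e2)
    utr3 <- c(ex2[2] + 1, ex2[2] + 150)
    ann <- gene_annotation("synth_tx", cds = rbind(ex1, ex2),
                           utr5 = rbind(utr5), utr3 = rbind(utr3),
                           introns = rbind(intr))
    codons <- c("ATG",
                sample(names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA != "*"],
                       n_codons - 1, replace = TRUE), "TAA")
    cds <- paste(codons, collapse = "")
    genomic_of_cds <- c(ex1[1]:ex1[2], ex2[1]:ex2[2])
    pick <- function(iv, n) sample(iv[1]:iv[2], n, replace = TRUE)
    noncoding <- data.frame(
      position = c(pick(utr5, 25), pick(intr, 50), pick(utr3, 25)),
      ref = NA_character_, alt = NA_character_,
      truth_class = rep(c("utr", "intronic", "utr"), c(25, 50, 25)),
      stringsAsFactors = FALSE)
    cpos <- sample(cds_len, 100, replace = TRUE)
    coding <- do.call(rbind, lapply(cpos, function(cp) {
      codon_i <- ceiling(cp / 3)
      within <- cp - 3 * (codon_i - 1)
      codon <- codons[codon_i]
      ref <- substr(codon, within, within)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      alt_codon <- codon
      substr(alt_codon, within, within) <- alt
      cls <- if (translate_codon(codon) == translate_codon(alt_codon))
        "coding_synonymous" else "coding_nonsynonymous"
      data.frame(position = genomic_of_cds[cp], ref = ref, alt = alt,
                 truth_class = cls, stringsAsFactors = FALSE)
    }))
    list(annotation = ann, cds_sequence = cds,
         positions = rbind(noncoding, coding))
  })
}
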