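# Synthetic-data generators. Every input the analysis modules consume can be
# generated here with the statistical structure the analyses assume, together
# with the ground truth needed for recovery tests. Identical seed + config
# always yields identical output.

#' Published per-family carriage counts for the plasmid survey
#'
#' The per-family counts of regulator-homologue-carrying plasmids reported
#' for the COMPASS plasmid collection (12,084 plasmids; 98 carriers, 0.8%),
#' used as the reference input for the survey arithmetic: 41/196
#' Pseudomonadaceae, 12/67 Piscirickettsiaceae, 21/29 Legionellaceae,
#' 0/3,621 Enterobacteriaceae, with the remaining carriers spread over other
#' families.
#'
#' @return Tibble with columns `family`, `carriers`, `total`.
#' @export
compass_family_counts <- function() {
  tibble(
    family = c("Pseudomonadaceae", "Piscirickettsiaceae", "Legionellaceae",
               "Enterobacteriaceae", "other"),
    carriers = c(41L, 12L, 21L, 0L, 24L),
    total = c(196L, 67L, 29L, 3621L, 8171L)
  )
}

#' Configuration for a synthetic plasmid survey
#'
#' Defaults reproduce the survey conditions of the published plasmid
#' collection: four focal families with the reported plasmid counts and
#' carriage probabilities (0.21, 0.18, 0.72, 0), log-normal plasmid sizes
#' with carriers drawn from the upper part of each family's size
#' distribution, and a conjugative/mobilizable/non-mobilizable mobility mix.
#'
#' @param taxa Tibble with columns `family`, `n_plasmids`, `carriage_prob`,
#'   and optionally `size_meanlog`, `size_sdlog`.
#' @param size_meanlog,size_sdlog Log-normal size model (bp) used for
#'   families that do not override it. Default centres at ~50 kb.
#' @param carrier_size_shift Added to `size_meanlog` for carrier plasmids
#'   (carriers sit at the large end of each family's distribution).
#' @param mobility_probs Named probabilities for mobility classes.
#' @param mobility_probs_carrier Optional override for carrier plasmids
#'   (e.g. to make carriers preferentially conjugative).
#' @param seed Integer seed; same seed and config give identical collections.
#' @return A list of class `rsm_survey_config`.
#' @export
survey_config <- function(taxa = NULL,
                          size_meanlog = log(5e4), size_sdlog = 0.8,
                          carrier_size_shift = 0.8,
                          mobility_probs = c(conjugative = 0.3,
                                             mobilizable = 0.25,
                                             non_mobilizable = 0.45),
                          mobility_probs_carrier = NULL,
                          seed = 1L) {
  if (is.null(taxa)) {
    taxa <- tibble(
      family = c("Pseudomonadaceae", "Piscirickettsiaceae",
                 "Legionellaceae", "Enterobacteriaceae"),
      n_plasmids = c(196L, 67L, 29L, 3621L),
      carriage_prob = c(0.21, 0.18, 0.72, 0)
    )
  }
  taxa <- as_tibble(taxa)
  if (nrow(taxa) == 0) abort("`taxa` must contain at least one family")
  if (any(taxa$n_plasmids < 0)) abort("plasmid counts must be >= 0")
  check_prob(taxa$carriage_prob, "carriage_prob")
  check_prob(mobility_probs, "mobility_probs")
  if (abs(sum(mobility_probs) - 1) > 1e-8) {
    abort("`mobility_probs` must sum to 1")
  }
  if (!is.null(mobility_probs_carrier)) {
    check_prob(mobility_probs_carrier, "mobility_probs_carrier")
    if (abs(sum(mobility_probs_carrier) - 1) > 1e-8) {
      abort("`mobility_probs_carrier` must sum to 1")
    }
  }
  if (!"size_meanlog" %in% names(taxa)) taxa$size_meanlog <- size_meanlog
  if (!"size_sdlog" %in% names(taxa)) taxa$size_sdlog <- size_sdlog
  structure(
    list(taxa = taxa, carrier_size_shift = carrier_size_shift,
         mobility_probs = mobility_probs,
         mobility_probs_carrier = mobility_probs_carrier,
         seed = as.integer(seed)),
    class = "rsm_survey_config"
  )
}

#' Simulate a plasmid collection
#'
#' Draws, per family, the configured number of plasmids with a Bernoulli
#' regulator-carriage flag, a log-normal length, and a mobility class
#' (optionally conditioned on carriage). The carriage flag is the ground
#' truth against which homologue detection is scored.
#'
#' @param config An `rsm_survey_config` from [survey_config()].
#' @return Tibble with `plasmid_id`, `family`, `length_bp`, `mobility`,
#'   `carries_rsm` (ground truth).
#' @export
sim_plasmid_collection <- function(config = survey_config()) {
  stopifnot(inherits(config, "rsm_survey_config"))
  set.seed(config$seed)
  mob_classes <- names(config$mobility_probs)
  out <- purrr::pmap_dfr(
    config$taxa,
    function(family, n_plasmids, carriage_prob, size_meanlog, size_sdlog, ...) {
      if (n_plasmids == 0) return(tibble())
      carries <- stats::runif(n_plasmids) < carriage_prob
      meanlog <- size_meanlog + ifelse(carries, config$carrier_size_shift, 0)
      len <- round(stats::rlnorm(n_plasmids, meanlog, size_sdlog))
      probs_c <- config$mobility_probs_carrier %||% config$mobility_probs
      mob <- character(n_plasmids)
      mob[carries] <- sample(mob_classes, sum(carries), TRUE, probs_c)
      mob[!carries] <- sample(mob_classes, sum(!carries), TRUE,
                              config$mobility_probs)
      tibble(
        family = family,
        length_bp = pmax(len, 1000),
        mobility = mob,
        carries_rsm = carries
      )
    }
  )
  out$plasmid_id <- sprintf("p%05d", seq_len(nrow(out)))
  dplyr::select(out, "plasmid_id", dplyr::everything())
}

#' Synthetic reference protein for homologue detection
#'
#' A fixed, synthetic 61-residue sequence with the approximate length and
#' composition of a CsrA/RsmA-family regulator. It is a stand-in reference
#' for alignment-based homologue screening in simulations and tests, not a
#' real protein.
#'
#' @return Tibble with columns `name`, `sequence`.
#' @export
rsm_reference_proteins <- function() {
  tibble(
    name = "rsm_family_synthetic_ref",
    sequence = paste0(
      "MLILTRRVGETLMIGDEVTVTVLGVKGNQVRIG",
      "VNAPKEVSVHREEIYQRIQAEKSQEPNS"
    )
  )
}

# Mutate a protein to a target identity by random substitutions.
mutate_protein <- function(sequence, identity) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n_mut <- round((1 - identity) * length(aa))
  if (n_mut > 0) {
    pos <- sample(length(aa), n_mut)
    alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V")
    aa[pos] <- vapply(aa[pos], function(x) sample(setdiff(alphabet, x), 1),
                      character(1))
  }
  paste(aa, collapse = "")
}

# A random protein with no relationship to the reference.
random_protein <- function(n) {
  alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Simulate plasmid protein complements for homologue detection
#'
#' Gives every plasmid a small set of random proteins; plasmids whose ground
#' truth is carriage additionally receive a mutated copy of the reference at
#' the requested amino acid identity.
#'
#' @param plasmids Tibble from [sim_plasmid_collection()] (needs
#'   `plasmid_id`, `carries_rsm`).
#' @param reference Reference tibble as from [rsm_reference_proteins()].
#' @param genes_per_plasmid Number of background proteins per plasmid.
#' @param homologue_identity Amino acid identity of planted homologues.
#' @param seed Integer seed.
#' @return Tibble with `plasmid_id`, `gene_id`, `protein`,
#'   `is_homologue_truth`.
#' @export
sim_plasmid_proteins <- function(plasmids,
                                 reference = rsm_reference_proteins(),
                                 genes_per_plasmid = 5,
                                 homologue_identity = 0.9,
                                 seed = 1L) {
  set.seed(seed)
  purrr::pmap_dfr(
    plasmids[c("plasmid_id", "carries_rsm")],
    function(plasmid_id, carries_rsm) {
      prot <- replicate(genes_per_plasmid,
                        random_protein(sample(80:300, 1)))
      is_hom <- rep(FALSE, genes_per_plasmid)
      if (carries_rsm) {
        prot <- c(prot, mutate_protein(reference$sequence[1],
                                       homologue_identity))
        is_hom <- c(is_hom, TRUE)
      }
      tibble(
        plasmid_id = plasmid_id,
        gene_id = paste0(plasmid_id, "_g", seq_along(prot)),
        protein = prot,
        is_homologue_truth = is_hom
      )
    }
  )
}

#' Configuration for a synthetic regulatory genome
#'
#' Defaults mirror the structure of the experimentally characterised
#' regulon: among target genes, 50% carry a full `AnGGA` site and 25% the
#' minimal `GGA` site (the remainder are indirect targets with no site);
#' direct targets show a +2 protein log2 fold change (higher abundance when
#' the regulator is absent, i.e. repression) with essentially no mRNA
#' change, on a small log-ratio noise floor.
#'
#' @param n_targets Number of regulated (target) genes.
#' @param n_background Number of unregulated background genes.
#' @param frac_full,frac_short Fractions of target genes planted with a full
#'   `AnGGA` or a minimal `GGA` site (must sum to <= 1; the remainder are
#'   indirect targets without a site).
#' @param exposure Structural context for planted motifs: `"apex"`,
#'   `"partial"`, `"occluded"` or `"linear"`.
#' @param effect_direct,effect_indirect Protein log2 fold-change shift for
#'   direct / indirect targets (contrast: regulator absent vs present, so a
#'   positive shift means repression by the regulator).
#' @param noise_sd Standard deviation of log2 fold-change noise (> 0).
#' @param mrna_effect_fraction Fraction of the protein effect that also
#'   appears at the mRNA layer (0 = purely post-transcriptional).
#' @param upstream_range Range (min, max) of upstream region lengths (nt).
#' @param orf_length ORF length (nt).
#' @param scrub_background Remove chance `GGA` occurrences outside planted
#'   constructs so that genes without a planted motif are truly motif-free
#'   (the default makes planted-site recovery exactly scoreable); set to
#'   `FALSE` to retain the analytic 1/64-per-position chance-GGA background
#'   of uniform sequence.
#' @param seed Integer seed.
#' @return A list of class `rsm_regulon_config`.
#' @export
regulon_config <- function(n_targets = 100, n_background = 100,
                           frac_full = 0.5, frac_short = 0.25,
                           exposure = "apex",
                           effect_direct = 2, effect_indirect = 2,
                           noise_sd = 0.1, mrna_effect_fraction = 0,
                           upstream_range = c(150, 400), orf_length = 500,
                           scrub_background = TRUE, seed = 1L) {
  check_prob(frac_full, "frac_full"); check_prob(frac_short, "frac_short")
  if (frac_full + frac_short > 1 + 1e-9) {
    abort("`frac_full` + `frac_short` must be <= 1")
  }
  exposure <- match.arg(exposure, c("apex", "partial", "occluded", "linear"))
  if (!all(is.finite(c(effect_direct, effect_indirect, noise_sd)))) {
    abort("effect sizes and noise must be finite")
  }
  if (upstream_range[1] < 30) {
    abort("upstream regions must be at least 30 nt (motif construct length)")
  }
  structure(
    list(n_targets = n_targets, n_background = n_background,
         frac_full = frac_full, frac_short = frac_short,
         exposure = exposure, effect_direct = effect_direct,
         effect_indirect = effect_indirect, noise_sd = noise_sd,
         mrna_effect_fraction = mrna_effect_fraction,
         upstream_range = upstream_range, orf_length = orf_length,
         scrub_background = scrub_background, seed = as.integer(seed)),
    class = "rsm_regulon_config"
  )
}

# Remove every GGA occurrence from a DNA string by mutating the middle G to T
# (T never matches a position of the GGA/AnGGA patterns, so no new motif can
# be created).
scrub_gga <- function(seq) {
  repeat {
    pos <- regexpr("GGA", seq, fixed = TRUE)
    if (pos < 0) return(seq)
    substr(seq, pos + 1, pos + 1) <- "T"
  }
}

# Build the motif construct (DNA) for one planted site. Returns the
# construct string and the 1-based motif coordinates within it. Stems are
# perfect complements chosen so that background bases cannot out-pair the
# designed hairpin and the maximum-pairing fold is the designed one.
motif_construct <- function(motif_class, exposure) {
  n_base <- if (motif_class == "FULL") {
    if (exposure == "linear") sample(c("A", "C", "G"), 1)
    else sample(c("A", "C", "G", "T"), 1)
  } else {
    NULL
  }
  motif <- if (motif_class == "FULL") paste0("A", n_base, "GGA") else "GGA"

  if (exposure == "apex") {
    if (motif_class == "FULL") {
      margin2 <- if (n_base == "T") "C" else "A"
      construct <- paste0("AAAAA", "GCCCCC", "A", motif, margin2,
                          "GGGGGC", "AAAAAA")
      m_start <- 5 + 6 + 1 + 1
    } else {
      construct <- paste0("AAAAAA", "GCCCCC", "A", motif, "A",
                          "GGGGGC", "AAAAAAA")
      m_start <- 6 + 6 + 1 + 1
    }
  } else if (exposure == "linear") {
    left <- if (motif_class == "FULL") 12 else 13
    construct <- paste0(strrep("A", left), motif,
                        strrep("A", 30 - left - nchar(motif)))
    m_start <- left + 1
  } else if (exposure == "occluded") {
    arm <- paste0("GC", motif, "CG")
    construct <- paste0(arm, "AAA", revcomp(arm))
    m_start <- 3
  } else { # partial: first two motif bases in the stem, rest in the loop
    armL <- paste0("CC", substr(motif, 1, 2))
    loop <- paste0(substr(motif, 3, nchar(motif)), "AAA")
    construct <- paste0(armL, loop, revcomp(armL))
    m_start <- 3
  }
  list(construct = construct, motif = motif,
       m_start = m_start, m_end = m_start + nchar(motif) - 1)
}

#' Simulate an annotated genome with planted regulator binding sites
#'
#' Lays out genes on a single forward-strand contig, each with an upstream
#' region and an ORF. Target genes assigned a motif class receive a designed
#' construct in mid-upstream presenting the motif in the configured
#' structural context (for the apex class, perfectly complementary 6-bp
#' stems fold the motif into a terminal hairpin loop). Ground-truth labels
#' (role, motif class, exposure, motif coordinates) are returned alongside.
#'
#' @param config An `rsm_regulon_config` from [regulon_config()].
#' @return List with `genome` (character scalar), `genes` (tibble:
#'   `gene_id`, `start`, `end`, `strand`), `truth` (tibble: `gene_id`,
#'   `role`, `motif_class`, `exposure`, `motif_start`, `motif_end`,
#'   `is_target`).
#' @export
sim_regulatory_genome <- function(config = regulon_config()) {
  stopifnot(inherits(config, "rsm_regulon_config"))
  set.seed(config$seed)
  n_full <- round(config$n_targets * config$frac_full)
  n_short <- round(config$n_targets * config$frac_short)
  n_indirect <- config$n_targets - n_full - n_short
  roles <- c(rep("direct", n_full + n_short), rep("indirect", n_indirect),
             rep("background", config$n_background))
  classes <- c(rep("FULL", n_full), rep("SHORT", n_short),
               rep("NONE", n_indirect + config$n_background))
  n_genes <- length(roles)
  ord <- sample(n_genes)
  roles <- roles[ord]; classes <- classes[ord]

  pieces <- character(n_genes)
  genes <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  offset <- 0L
  for (g in seq_len(n_genes)) {
    u <- sample(config$upstream_range[1]:config$upstream_range[2], 1)
    upstream <- random_dna(u)
    orf <- random_dna(config$orf_length)
    if (config$scrub_background) {
      upstream <- scrub_gga(upstream)
      orf <- scrub_gga(orf)
    }
    m_start <- NA_integer_; m_end <- NA_integer_
    expo <- NA_character_
    if (classes[g] != "NONE") {
      mc <- motif_construct(classes[g], config$exposure)
      cs <- max(1L, (u - nchar(mc$construct)) %/% 2L)
      substr(upstream, cs, cs + nchar(mc$construct) - 1L) <- mc$construct
      # no G runs directly upstream of the construct: a genomic ...GG
      # abutting the construct's leading A would create a spurious motif
      if (cs >= 3) substr(upstream, cs - 2L, cs - 1L) <- "CC"
      m_start <- offset + cs + mc$m_start - 1L
      m_end <- offset + cs + mc$m_end - 1L
      expo <- config$exposure
    }
    start <- offset + u + 1L
    end <- start + config$orf_length - 1L
    pieces[g] <- paste0(upstream, orf)
    genes[[g]] <- tibble(gene_id = sprintf("gene%04d", g),
                         start = start, end = end, strand = "+")
    truth[[g]] <- tibble(
      gene_id = sprintf("gene%04d", g), role = roles[g],
      motif_class = classes[g], exposure = expo,
      motif_start = m_start, motif_end = m_end,
      is_target = roles[g] != "background"
    )
    offset <- offset + u + config$orf_length
  }
  genome <- paste(pieces, collapse = "")
  truth <- dplyr::bind_rows(truth)
  if (config$scrub_background) {
    # second pass: motifs can form across piece junctions that the
    # per-piece scrub cannot see; remove them, protecting planted motifs
    genome <- scrub_gga_protected(
      genome, truth$motif_start[!is.na(truth$motif_start)],
      truth$motif_end[!is.na(truth$motif_end)]
    )
  }
  list(
    genome = genome,
    genes = dplyr::bind_rows(genes),
    truth = truth
  )
}

# Remove GGA occurrences outside the protected [start, end] intervals.
scrub_gga_protected <- function(genome, protect_start, protect_end) {
  repeat {
    m <- gregexpr("GGA", genome, fixed = TRUE)[[1]]
    if (m[1] < 0) return(genome)
    protected <- vapply(m, function(p) {
      any(p <= protect_end & (p + 2) >= protect_start)
    }, logical(1))
    if (all(protected)) return(genome)
    p <- m[!protected][1]
    substr(genome, p + 1, p + 1) <- "T"
  }
}

#' Simulate paired mRNA and protein fold-change tables
#'
#' Target genes receive the configured protein log2 fold-change shift
#' (direct and indirect effects separately) plus Gaussian noise; the mRNA
#' layer receives only the configured fraction of the effect (0 by default:
#' a purely post-transcriptional signature). Adjusted p-values are
#' Benjamini-Hochberg-corrected two-sided z-test p-values under the same
#' effect/noise model.
#'
#' @param truth Ground-truth tibble from [sim_regulatory_genome()].
#' @param config The `rsm_regulon_config` used (supplies effects, noise and
#'   seed; the expression seed is offset so genome and expression draws are
#'   independent).
#' @return List with tibbles `mrna` and `protein`, each with `gene_id`,
#'   `log2fc`, `padj`, `layer`.
#' @export
sim_expression_tables <- function(truth, config) {
  stopifnot(inherits(config, "rsm_regulon_config"))
  if (config$noise_sd <= 0) abort("`noise_sd` must be > 0")
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  shift <- dplyr::case_when(
    truth$role == "direct" ~ config$effect_direct,
    truth$role == "indirect" ~ config$effect_indirect,
    TRUE ~ 0
  )
  layer_table <- function(mu) {
    fc <- stats::rnorm(n, mu, config$noise_sd)
    p <- 2 * stats::pnorm(-abs(fc / config$noise_sd))
    tibble(gene_id = truth$gene_id, log2fc = fc,
           padj = stats::p.adjust(p, method = "BH"))
  }
  protein <- layer_table(shift)
  protein$layer <- "protein"
  mrna <- layer_table(shift * config$mrna_effect_fraction)
  mrna$layer <- "mRNA"
  list(mrna = mrna, protein = protein)
}

#' Simulate SPR responses for a panel of oligos
#'
#' Generates per-oligo, per-variant responses that follow the qualitative
#' binding rules the predictor encodes: a motif open at a hairpin apex binds
#' strongly (high percent Rmax), a linear or partially occluded motif binds
#' transiently (intermediate), a scrambled or occluded site gives no
#' binding, and binding-surface mutants (H43A, R44A) are attenuated by one
#' level. Additive Gaussian noise is applied on the percent scale and
#' responses are floored at zero.
#'
#' @param oligos Tibble with `oligo_id`, `motif_class` (`FULL`/`SHORT`/
#'   `NONE`), `exposure` (`APEX`/`PARTIAL`/`OCCLUDED`/`LINEAR`).
#' @param variants Protein variants to simulate.
#' @param concentration_nM Analyte concentration annotation.
#' @param ru_immob Ligand immobilisation level (RU).
#' @param mw_ligand,mw_analyte Ligand / analyte molecular weights (Da); the
#'   analyte default is a regulator homodimer.
#' @param mean_pct Named means of percent Rmax per binding call.
#' @param noise_sd Noise standard deviation on the percent scale.
#' @param replicates Technical replicates per oligo x variant.
#' @param seed Integer seed.
#' @return Tibble of measurements ready for [spr_percent_rmax()], with the
#'   generating call in `call_truth`.
#' @export
sim_spr_responses <- function(oligos,
                              variants = c("WT", "H43A", "R44A"),
                              concentration_nM = 100,
                              ru_immob = 50, mw_ligand = 9200,
                              mw_analyte = 13800,
                              mean_pct = c(STRONG = 85, TRANSIENT = 30,
                                           NONE = 1),
                              noise_sd = 4, replicates = 2, seed = 1L) {
  if (!all(c("oligo_id", "motif_class", "exposure") %in% names(oligos))) {
    abort("`oligos` needs columns oligo_id, motif_class, exposure")
  }
  bad <- setdiff(oligos$exposure, c("APEX", "PARTIAL", "OCCLUDED", "LINEAR"))
  if (length(bad) > 0) {
    abort(sprintf("unknown exposure class: %s", paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  rmax <- theoretical_rmax(mw_analyte, mw_ligand, ru_immob)
  grid <- tidyr::expand_grid(
    oligos, variant = variants, replicate = seq_len(replicates)
  )
  grid$call_truth <- purrr::pmap_chr(
    grid[c("motif_class", "exposure", "variant")],
    function(motif_class, exposure, variant) {
      predict_binding(motif_class, exposure, variant)
    }
  )
  pct <- mean_pct[grid$call_truth] + stats::rnorm(nrow(grid), 0, noise_sd)
  grid$r_obs <- pmax(0, pct / 100 * rmax)
  grid$concentration_nM <- concentration_nM
  grid$ru_immob <- ru_immob
  grid$mw_ligand <- mw_ligand
  grid$mw_analyte <- mw_analyte
  grid$stoichiometry <- 1
  grid
}

#' Simulate a labelled homologue alignment on a star phylogeny
#'
#' Chromosomal sequences are drawn close to a common ancestor (tight
#' cluster), plasmid sequences are more diverged, emulating the observed
#' pattern that plasmid-borne regulator homologues are more divergent than
#' chromosomal ones.
#'
#' @param n_chromosome,n_plasmid Sequences per origin.
#' @param length_nt Alignment length.
#' @param chromosome_rate,plasmid_rate Per-site substitution probability on
#'   the branch leading to each sequence.
#' @param seed Integer seed.
#' @return Alignment tibble with `id`, `origin`, `seq` (equal lengths, no
#'   gaps).
#' @export
sim_homologue_alignment <- function(n_chromosome = 10, n_plasmid = 10,
                                    length_nt = 300,
                                    chromosome_rate = 0.02,
                                    plasmid_rate = 0.15, seed = 1L) {
  set.seed(seed)
  ancestor <- strsplit(random_dna(length_nt), "", fixed = TRUE)[[1]]
  evolve <- function(rate) {
    s <- ancestor
    hit <- stats::runif(length(s)) < rate
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
    paste(s, collapse = "")
  }
  tibble(
    id = c(sprintf("chr%02d", seq_len(n_chromosome)),
           sprintf("pls%02d", seq_len(n_plasmid))),
    origin = c(rep("chromosome", n_chromosome), rep("plasmid", n_plasmid)),
    seq = c(replicate(n_chromosome, evolve(chromosome_rate)),
            replicate(n_plasmid, evolve(plasmid_rate)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
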