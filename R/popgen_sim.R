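# Seeded simulator for a segregating octoploid population carrying a dominant
# deletion locus: genotypes, gene-level counts, GC/MS peak tables, marker and
# SSR panels, qPCR CTs and pileup summaries, all with the statistical
# structure the discovery pipeline assumes. One master seed feeds named
# substreams per operation, so outputs are reproducible and independent.

#' Describe the causal locus
#'
#' The trait behaves as a single dominant locus: the producer parent
#' carries one functional copy (simplex in the octoploid genome) and the
#' non-producer parent carries none, consistent with a hemizygous deletion.
#' Dosage above one is not modelled because observed segregation is ~1:1.
#'
#' @param inheritance Only `"dominant_simplex"` is supported.
#' @param carrier_parent_id Id of the carrier (producer) parent.
#' @param description Free-text note.
#' @return An object of class `locus_model`.
#' @export
locus_model <- function(inheritance = "dominant_simplex",
                        carrier_parent_id = "parent_producer",
                        description = "hemizygous deletion of the causal gene") {
  inheritance <- match.arg(inheritance)
  structure(list(inheritance = inheritance,
                 carrier_parent_id = carrier_parent_id,
                 description = description),
            class = "locus_model")
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' a 16-genotype RNA-seq panel (2 parents + 14 progeny), ~2,000 genes of
#' which one is the causal deletion gene and 50 are phenotype-independent
#' decoys emulating subgenome presence/absence segregation, negative
#' binomial counts with log-uniform per-gene means, an abundant causal
#' transcript, an 11-fold inductive-environment effect and a 21-fold
#' ripening effect on the causal gene.
#'
#' @param n_progeny Progeny in the default panel (default 14; the full
#'   panel adds the two parents).
#' @param n_genes Number of genes (default 2000).
#' @param causal_gene_index 1-based index of the causal gene
#'   (default 1042).
#' @param n_decoy_genes Phenotype-independent presence/absence decoy genes
#'   (default 50).
#' @param nb_mean_range Range of per-gene negative binomial mean counts;
#'   means are log-uniform in this range (default 5-500).
#' @param nb_dispersion Shared NB dispersion (`size = 1/dispersion`;
#'   default 0.3).
#' @param causal_mean_rpkm Mean RPKM of the causal gene in carriers at the
#'   ripe stage in the inductive environment (default 150: the causal
#'   transcript is a highly abundant one).
#' @param detect_noise_sd SD of multiplicative log-normal noise on carrier
#'   volatile signal (default 0.1).
#' @param gene_length_range Transcript length range in bp (default
#'   500-5000).
#' @param library_size_range Mapped reads per genotype (default
#'   3e5-8.5e5).
#' @param volatile_baseline Maximum normalized response emitted by a
#'   non-carrier (background noise ceiling; default 0.01).
#' @param volatile_signal Base normalized response of a carrier (trend
#'   shape multiplies this; default 0.5).
#' @param env_effect_fold Inductive : non-inductive volatile and causal
#'   expression fold (default 11).
#' @param ripening_fold Ripe : blushing causal expression fold
#'   (default 21).
#' @param trend_probs Probabilities of the four producer trend classes
#'   (PEAK, VALLEY, DECREASE, INCREASE).
#' @param ct_noise_sd Gaussian noise SD on simulated CT values in cycles
#'   (default 0.05).
#' @param seed Master seed; fully determines all outputs.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_progeny = 14L, n_genes = 2000L,
                       causal_gene_index = 1042L, n_decoy_genes = 50L,
                       nb_mean_range = c(5, 500), nb_dispersion = 0.3,
                       causal_mean_rpkm = 150, detect_noise_sd = 0.1,
                       gene_length_range = c(500L, 5000L),
                       library_size_range = c(3e5, 8.5e5),
                       volatile_baseline = 0.01, volatile_signal = 0.5,
                       env_effect_fold = 11, ripening_fold = 21,
                       trend_probs = c(PEAK = 0.50, VALLEY = 0.28,
                                       DECREASE = 0.17, INCREASE = 0.05),
                       ct_noise_sd = 0.05, seed = 1L) {
  cfg <- list(n_progeny = as.integer(n_progeny), n_genes = as.integer(n_genes),
              causal_gene_index = as.integer(causal_gene_index),
              n_decoy_genes = as.integer(n_decoy_genes),
              nb_mean_range = nb_mean_range, nb_dispersion = nb_dispersion,
              causal_mean_rpkm = causal_mean_rpkm,
              detect_noise_sd = detect_noise_sd,
              gene_length_range = gene_length_range,
              library_size_range = library_size_range,
              volatile_baseline = volatile_baseline,
              volatile_signal = volatile_signal,
              env_effect_fold = env_effect_fold,
              ripening_fold = ripening_fold, trend_probs = trend_probs,
              ct_noise_sd = ct_noise_sd, seed = as.integer(seed))
  if (cfg$causal_gene_index < 1L || cfg$causal_gene_index > cfg$n_genes) {
    stop("causal_gene_index must lie in [1, n_genes]", call. = FALSE)
  }
  if (cfg$n_decoy_genes >= cfg$n_genes) {
    stop("n_decoy_genes must be < n_genes", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0 || any(cfg$nb_mean_range <= 0)) {
    stop("count-model parameters must be positive", call. = FALSE)
  }
  if (abs(sum(cfg$trend_probs) - 1) > 1e-8 || length(cfg$trend_probs) != 4L) {
    stop("trend_probs must be 4 probabilities summing to 1", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

trend_levels <- c("PEAK", "VALLEY", "DECREASE", "INCREASE")

# seasonal shapes over three harvests, per producer trend class
trend_shape <- function(class, n_harvests = 3L) {
  base <- switch(class,
                 PEAK = c(1, 3, 1),
                 VALLEY = c(3, 1, 3),
                 DECREASE = c(3, 1, 1),
                 INCREASE = c(1, 2, 4),
                 stop("unknown trend class: ", class, call. = FALSE))
  if (n_harvests == 3L) return(base)
  stats::approx(x = 1:3, y = base,
                xout = seq(1, 3, length.out = n_harvests))$y
}

#' Simulate progeny of a cross segregating the causal locus
#'
#' Each progeny's carrier state is an independent Bernoulli draw with the
#' Mendelian probability implied by the cross: 0.5 for the F1 (simplex
#' carrier x null) and for a backcross of a carrier F1 to the null parent,
#' 0.75 for a backcross of a carrier F1 to the simplex producer parent.
#' Carriers receive a seasonal trend class; non-carriers are NONPRODUCER.
#'
#' @param locus A [locus_model()].
#' @param cross One of `"F1"`, `"BC1_to_producer"`, `"BC1_to_nonproducer"`.
#' @param n Number of progeny (`>= 1`).
#' @param seed Seed for this draw.
#' @param trend_probs Trend-class probabilities for carriers.
#' @return Data frame of progeny: `id`, `role`, `carrier`, `trend_class`,
#'   `env_schedule`.
#' @export
simulate_cross <- function(locus, cross = c("F1", "BC1_to_producer",
                                            "BC1_to_nonproducer"),
                           n, seed = 1L,
                           trend_probs = c(PEAK = 0.50, VALLEY = 0.28,
                                           DECREASE = 0.17, INCREASE = 0.05)) {
  stopifnot(inherits(locus, "locus_model"))
  cross <- match.arg(cross)
  assert_scalar_number(n, "n", min = 1)
  p_carrier <- switch(cross, F1 = 0.5, BC1_to_nonproducer = 0.5,
                      BC1_to_producer = 0.75)
  with_substream(seed, paste0("cross_", cross), {
    carrier <- stats::runif(n) < p_carrier
    trend <- rep(NA_character_, n)
    if (any(carrier)) {
      trend[carrier] <- sample(trend_levels, sum(carrier), replace = TRUE,
                               prob = trend_probs)
    }
    data.frame(
      id = sprintf("%s_%03d", sub("_to_.*$", "", cross), seq_len(n)),
      role = sub("_to_.*$", "", cross),
      carrier = carrier,
      trend_class = ifelse(carrier, trend, "NONPRODUCER"),
      env_schedule = "b,b,b",
      stringsAsFactors = FALSE
    )
  })
}

#' Build the 16-genotype study panel
#'
#' Two parents plus `n_progeny` progeny with the panel composition fixed at
#' 11 producers and 5 non-producers for the default `n_progeny = 14`
#' (10 carrier and 4 non-carrier progeny, in seeded random order). The
#' composition is fixed rather than redrawn because the sequenced panel in
#' a real study is selected from the phenotyped population, not sampled;
#' random segregation itself is the business of [simulate_cross()].
#'
#' @param cfg A [sim_config()].
#' @return Data frame of genotypes, parents first.
#' @export
simulate_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n_carrier <- round(cfg$n_progeny * 10 / 14)
  n_null <- cfg$n_progeny - n_carrier
  with_substream(cfg$seed, "panel", {
    carrier <- sample(rep(c(TRUE, FALSE), c(n_carrier, n_null)))
    trend <- rep("NONPRODUCER", cfg$n_progeny)
    trend[carrier] <- sample(trend_levels, sum(carrier), replace = TRUE,
                             prob = cfg$trend_probs)
    progeny <- data.frame(
      id = sprintf("F1_%03d", seq_len(cfg$n_progeny)),
      role = "F1", carrier = carrier, trend_class = trend,
      env_schedule = "b,b,b", stringsAsFactors = FALSE
    )
    parents <- data.frame(
      id = c("parent_producer", "parent_nonproducer"),
      role = c("parent_producer", "parent_nonproducer"),
      carrier = c(TRUE, FALSE),
      trend_class = c("PEAK", "NONPRODUCER"),
      env_schedule = "b,b,b", stringsAsFactors = FALSE
    )
    rbind(parents, progeny)
  })
}

# convert an RPKM target into an expected count for one genotype
rpkm_to_mu <- function(rpkm, length_bp, library_size) {
  rpkm * length_bp * library_size / 1e9
}

# per-gene attributes are drawn once from the master seed so that every
# stage / environment sees the same genes
gene_attributes <- function(cfg) {
  with_substream(cfg$seed, "genes", {
    lengths <- round(stats::runif(cfg$n_genes, cfg$gene_length_range[1L],
                                  cfg$gene_length_range[2L]))
    means <- exp(stats::runif(cfg$n_genes, log(cfg$nb_mean_range[1L]),
                              log(cfg$nb_mean_range[2L])))
    decoy_pool <- setdiff(seq_len(cfg$n_genes), cfg$causal_gene_index)
    decoys <- sort(sample(decoy_pool, cfg$n_decoy_genes))
    list(lengths = lengths, means = means, decoys = decoys)
  })
}

#' Simulate a gene-level expression matrix for a set of genotypes
#'
#' Background genes draw negative binomial counts around a shared per-gene
#' mean scaled by library size. The causal gene is a deletion: exactly zero
#' counts in every non-carrier; in carriers it draws NB counts at a mean
#' RPKM of `causal_mean_rpkm`, divided by `ripening_fold` at blushing (and
#' by a further factor of 5 at green), and by `env_effect_fold` in the
#' non-inductive environment. Decoy genes are abundant in a random half of
#' the genotypes irrespective of carrier status, emulating subgenome
#' presence/absence segregation.
#'
#' @param genotypes Data frame from [simulate_panel()] or
#'   [simulate_cross()].
#' @param cfg A [sim_config()].
#' @param stage Developmental stage: `"green"`, `"blushing"` or `"ripe"`.
#' @param environment `"b"` (inductive, default) or `"a"` (non-inductive).
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(genotypes, cfg = sim_config(),
                                stage = c("ripe", "blushing", "green"),
                                environment = c("b", "a")) {
  stopifnot(inherits(cfg, "sim_config"), nrow(genotypes) > 0L)
  stage <- match.arg(stage)
  environment <- match.arg(environment)
  attrs <- gene_attributes(cfg)
  n_s <- nrow(genotypes)
  size <- 1 / cfg$nb_dispersion
  stage_factor <- switch(stage, ripe = 1, blushing = 1 / cfg$ripening_fold,
                         green = 1 / (5 * cfg$ripening_fold))
  env_factor <- if (environment == "b") 1 else 1 / cfg$env_effect_fold
  with_substream(cfg$seed, paste0("expr_", stage, "_", environment, "_", n_s), {
    libs <- stats::runif(n_s, cfg$library_size_range[1L],
                         cfg$library_size_range[2L])
    lib_scale <- libs / mean(cfg$library_size_range)
    counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_s,
                     dimnames = list(sprintf("gene%05d", seq_len(cfg$n_genes)),
                                     genotypes$id))
    for (s in seq_len(n_s)) {
      counts[, s] <- stats::rnbinom(cfg$n_genes, size = size,
                                    mu = attrs$means * lib_scale[s])
    }
    # decoys: presence in a random half of genotypes, independent of carrier
    present <- matrix(stats::runif(length(attrs$decoys) * n_s) < 0.5,
                      nrow = length(attrs$decoys))
    for (j in seq_along(attrs$decoys)) {
      g <- attrs$decoys[j]
      mu <- rpkm_to_mu(cfg$causal_mean_rpkm, attrs$lengths[g], libs)
      row <- stats::rnbinom(n_s, size = size, mu = mu)
      row[!present[j, ]] <- 0L
      counts[g, ] <- row
    }
    # causal gene: hemizygous deletion
    g <- cfg$causal_gene_index
    mu <- rpkm_to_mu(cfg$causal_mean_rpkm * stage_factor * env_factor,
                     attrs$lengths[g], libs)
    row <- stats::rnbinom(n_s, size = size, mu = mu)
    row[!genotypes$carrier] <- 0L
    counts[g, ] <- row
    expression_matrix(counts, attrs$lengths, libs)
  })
}

#' Id of the planted causal gene
#'
#' @param cfg A [sim_config()].
#' @return Gene id string of the causal deletion gene.
#' @export
causal_gene_id <- function(cfg = sim_config()) {
  sprintf("gene%05d", cfg$causal_gene_index)
}

#' Simulate GC/MS peak tables across harvests
#'
#' Each genotype x harvest yields two technical replicates with an
#' internal-standard area and an analyte area. Non-carriers emit only
#' baseline noise (normalized response never above `volatile_baseline`);
#' carriers emit `volatile_signal` shaped by their trend class across the
#' season, multiplied by the environment effect of each harvest
#' (`env_effect_fold` lower in environment "a") under log-normal noise.
#'
#' @param genotypes Data frame of genotypes.
#' @param cfg A [sim_config()].
#' @param n_harvests Number of harvests, `>= 3` (phenotype calling
#'   requires three).
#' @return Data frame peak table: `genotype_id`, `harvest_id`,
#'   `environment`, `replicate`, `gd_area`, `is_area`.
#' @export
simulate_volatile_tables <- function(genotypes, cfg = sim_config(),
                                     n_harvests = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_harvests < 3L) {
    stop("n_harvests must be >= 3 (non-producer calling needs 3 harvests)",
         call. = FALSE)
  }
  with_substream(cfg$seed, paste0("volatiles_", n_harvests), {
    rows <- vector("list", nrow(genotypes))
    for (i in seq_len(nrow(genotypes))) {
      g <- genotypes[i, ]
      envs <- strsplit(g$env_schedule, ",", fixed = TRUE)[[1L]]
      envs <- rep_len(envs, n_harvests)
      shape <- if (g$carrier) trend_shape(g$trend_class, n_harvests) else NULL
      per <- vector("list", n_harvests)
      for (h in seq_len(n_harvests)) {
        is_area <- pmax(1000, stats::rnorm(2L, 50000, 2000))
        if (g$carrier) {
          env_mult <- if (envs[h] == "a") 1 / cfg$env_effect_fold else 1
          resp <- cfg$volatile_signal * shape[h] * env_mult *
            exp(stats::rnorm(2L, 0, cfg$detect_noise_sd))
        } else {
          resp <- stats::runif(2L, 0, cfg$volatile_baseline)
        }
        per[[h]] <- data.frame(genotype_id = g$id,
                               harvest_id = sprintf("H%d", h),
                               environment = envs[h],
                               replicate = 1:2,
                               gd_area = resp * is_area,
                               is_area = is_area,
                               stringsAsFactors = FALSE)
      }
      rows[[i]] <- do.call(rbind, per)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate the PCR-marker and SSR panels
#'
#' The gene-based PCR amplicon is present exactly in carriers (the marker
#' sits inside the deleted region); the positive control always amplifies.
#' The linked SSR allele 205 is present exactly in carriers, allele 209 is
#' monomorphic (present in everyone), and alleles 215 / 219 segregate
#' independently of carrier status.
#'
#' @param genotypes Data frame of genotypes.
#' @param seed Seed for the unlinked 215/219 assignment.
#' @return List with `markers` (genotype_id, amplicon_present,
#'   control_present) and `ssr` (genotype_id, alleles as comma-separated
#'   sizes).
#' @export
simulate_marker_panel <- function(genotypes, seed = 1L) {
  if (nrow(genotypes) == 0L) stop("no genotypes", call. = FALSE)
  with_substream(seed, "markers", {
    markers <- data.frame(genotype_id = genotypes$id,
                          amplicon_present = genotypes$carrier,
                          control_present = TRUE,
                          stringsAsFactors = FALSE)
    has215 <- stats::runif(nrow(genotypes)) < 0.5
    has219 <- stats::runif(nrow(genotypes)) < 0.5
    alleles <- vapply(seq_len(nrow(genotypes)), function(i) {
      a <- c(if (genotypes$carrier[i]) 205L, 209L,
             if (has215[i]) 215L, if (has219[i]) 219L)
      paste(a, collapse = ",")
    }, character(1L))
    list(markers = markers,
         ssr = data.frame(genotype_id = genotypes$id, alleles = alleles,
                          stringsAsFactors = FALSE))
  })
}

#' Simulate per-site pileup summaries for SNP filtering
#'
#' A planted fraction of sites is constructed to satisfy the SNP criteria
#' (depth >= `min_depth` and non-reference fraction >= `min_nonref_frac`
#' in at least `min_genotypes` genotypes); the remainder draw Poisson
#' depths and binomial non-reference counts at a heterozygous-like
#' fraction that essentially never reaches the 95% criterion.
#'
#' @param n_sites Number of sites (`>= 1`).
#' @param n_genotypes Number of genotypes.
#' @param cfg A [sim_config()] (supplies the seed when `seed` is missing).
#' @param seed Seed for this draw.
#' @param frac_pass Fraction of sites planted to pass (default 0.3).
#' @param min_depth,min_nonref_frac,min_genotypes Criteria the planted
#'   sites are built to satisfy.
#' @return List with `sites` (long-format pileup data frame) and
#'   `planted_pass` (logical per site).
#' @export
simulate_pileups <- function(n_sites, n_genotypes = 16L, cfg = sim_config(),
                             seed = cfg$seed, frac_pass = 0.3,
                             min_depth = 10L, min_nonref_frac = 0.95,
                             min_genotypes = 2L) {
  assert_scalar_number(n_sites, "n_sites", min = 1)
  ids <- sprintf("G%02d", seq_len(n_genotypes))
  with_substream(seed, "pileups", {
    planted <- stats::runif(n_sites) < frac_pass
    rows <- vector("list", n_sites)
    bases <- c("A", "C", "G", "T")
    for (s in seq_len(n_sites)) {
      ref <- sample(bases, 1L)
      alt <- sample(setdiff(bases, ref), 1L)
      depth <- stats::rpois(n_genotypes, 8)
      nonref <- stats::rbinom(n_genotypes, depth, 0.35)
      if (planted[s]) {
        k <- sample(min_genotypes:min(n_genotypes, min_genotypes + 4L), 1L)
        who <- sample(n_genotypes, k)
        depth[who] <- min_depth + stats::rpois(k, 20)
        nonref[who] <- depth[who]  # fraction 1 >= any min_nonref_frac
      }
      rows[[s]] <- data.frame(chrom = "chr1", pos = s * 10L, ref = ref,
                              alt = alt, genotype_id = ids,
                              depth = depth, nonref_count = nonref,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    list(sites = out, planted_pass = planted)
  })
}

#' Simulate comparative-CT qPCR measurements
#'
#' Triplicate CT values for a target and a housekeeping gene. In the
#' `"stage_pair"` design, a carrier is measured at blushing (calibrator)
#' and ripe, with a true ripe:blushing fold of `fold`. In the
#' `"genotype_panel"` design every genotype is measured against the
#' producer parent as calibrator; non-carriers never amplify the target
#' (CT is NA), reflecting the deletion.
#'
#' @param genotypes Data frame of genotypes.
#' @param cfg A [sim_config()] (supplies CT noise SD and default fold).
#' @param design `"stage_pair"` or `"genotype_panel"`.
#' @param fold True fold change for the stage pair (default
#'   `cfg$ripening_fold`).
#' @param seed Seed for this draw.
#' @return Long data frame: `condition`, `gene`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(genotypes, cfg = sim_config(),
                          design = c("stage_pair", "genotype_panel"),
                          fold = cfg$ripening_fold, seed = cfg$seed) {
  design <- match.arg(design)
  noise <- function(n) stats::rnorm(n, 0, cfg$ct_noise_sd)
  with_substream(seed, paste0("qpcr_", design), {
    if (design == "stage_pair") {
      hk <- 20
      dct_cal <- 5                       # blushing
      dct_sam <- dct_cal - log2(fold)    # ripe
      out <- rbind(
        data.frame(condition = "blushing", gene = "housekeeping",
                   replicate = 1:3, ct = hk + noise(3L)),
        data.frame(condition = "blushing", gene = "target",
                   replicate = 1:3, ct = hk + dct_cal + noise(3L)),
        data.frame(condition = "ripe", gene = "housekeeping",
                   replicate = 1:3, ct = hk + noise(3L)),
        data.frame(condition = "ripe", gene = "target",
                   replicate = 1:3, ct = hk + dct_sam + noise(3L))
      )
    } else {
      rows <- lapply(seq_len(nrow(genotypes)), function(i) {
        g <- genotypes[i, ]
        hk <- 20 + noise(3L)
        tg <- if (g$carrier) 25 + noise(3L) else rep(NA_real_, 3L)
        rbind(data.frame(condition = g$id, gene = "housekeeping",
                         replicate = 1:3, ct = hk),
              data.frame(condition = g$id, gene = "target",
                         replicate = 1:3, ct = tg))
      })
      out <- do.call(rbind, rows)
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate the full study dataset
#'
#' Bundles the panel genotypes with ripe-stage expression, a three-harvest
#' volatile peak table, marker and SSR panels, a genotype-panel qPCR table
#' and a pileup table, all driven by the master seed.
#'
#' @param cfg A [sim_config()].
#' @param n_pileup_sites Sites in the pileup table (default 200).
#' @return List of class `sim_population` with elements `genotypes`,
#'   `expression`, `volatiles`, `markers`, `ssr`, `qpcr`, `pileups`,
#'   `cfg`.
#' @export
simulate_population <- function(cfg = sim_config(), n_pileup_sites = 200L) {
  genotypes <- simulate_panel(cfg)
  mk <- simulate_marker_panel(genotypes, seed = cfg$seed)
  structure(list(
    genotypes = genotypes,
    expression = simulate_expression(genotypes, cfg, stage = "ripe"),
    volatiles = simulate_volatile_tables(genotypes, cfg, n_harvests = 3L),
    markers = mk$markers,
    ssr = mk$ssr,
    qpcr = simulate_qpcr(genotypes, cfg, design = "genotype_panel"),
    pileups = simulate_pileups(n_pileup_sites,
                               n_genotypes = nrow(genotypes), cfg = cfg)$sites,
    cfg = cfg
  ), class = "sim_population")
}
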