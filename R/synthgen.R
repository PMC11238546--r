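# Synthetic-data generators with planted ground truth.
#
# Raw sequencing and ICP-MS data for these experiments are not deposited,
# so every downstream stage is exercised against generated inputs whose
# true parameters are known: planted gene copies-per-genome for the omics
# quantification, planted concentration-response coefficients for the
# dissolution kinetics, and planted basalt effects / EDDHA slopes for the
# soil incubations. Noise-free ("expectation") modes give exact oracle
# fixtures; seeded stochastic modes support parameter-recovery and power
# checks. One global seed is split into deterministic per-generator
# substreams so modules stay independently reproducible.

#' Specification for a synthetic omics hit-table experiment
#'
#' @param genes Data.frame with columns `orthologue`, `class`,
#'   `subject_length_aa` (>= 50), `copies_basalt`, `copies_soil`
#'   (planted copies per genome on each substrate, >= 0). Default: a
#'   small panel of desferrioxamine-pathway and other siderophore genes.
#' @param n_samples_basalt,n_samples_soil Samples per substrate.
#' @param rpoa_subject_length_aa Length of the rpoA subject protein (aa).
#' @param read_length_mean,read_length_sd Read length distribution (bp);
#'   truncated normal with a 50 bp floor.
#' @param sequencing_depth Reads per sample (>= 1). Depths are not
#'   reported for the study's libraries; the default 5000 is an
#'   arbitrary, documented choice adequate for recovery tests.
#' @param genus_labels Data.frame with `genus`, `weight` (community
#'   fraction) and `desB_carriage` (probability a genome of that genus
#'   carries desB) used for genus-resolved desB/rpoA simulation.
#' @param decoy_fraction Extra decoy hits (as a fraction of true hits)
#'   with E-values log-uniform between `evalue_decoy_max` and
#'   `evalue_true_max` — above the 1e-5 analysis cutoff but below the
#'   1e-3 annotation cutoff, so the filter has work to do.
#' @param evalue_true_max,evalue_decoy_max E-value bounds for true and
#'   decoy hits.
#' @param genome_equivalents Genome equivalents per sample in
#'   expectation mode (scales expected copy counts).
#' @param seed Global seed.
#' @return Object of class `omics_sim_spec`.
#' @export
omics_sim_spec <- function(genes = default_gene_panel(),
                           n_samples_basalt = 4,
                           n_samples_soil = 4,
                           rpoa_subject_length_aa = 330,
                           read_length_mean = 150,
                           read_length_sd = 20,
                           sequencing_depth = 5000,
                           genus_labels = NULL,
                           decoy_fraction = 0,
                           evalue_true_max = 1e-6,
                           evalue_decoy_max = 1e-3,
                           genome_equivalents = 100,
                           seed = 1) {
  need <- c("orthologue", "class", "subject_length_aa",
            "copies_basalt", "copies_soil")
  missing <- setdiff(need, names(genes))
  if (length(missing)) {
    stop("genes is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(genes$subject_length_aa < 50) || rpoa_subject_length_aa < 50) {
    stop("subject lengths must be >= 50 aa", call. = FALSE)
  }
  if (any(genes$copies_basalt < 0) || any(genes$copies_soil < 0)) {
    stop("planted copies-per-genome must be >= 0", call. = FALSE)
  }
  if (sequencing_depth < 1) stop("sequencing depth must be >= 1",
                                 call. = FALSE)
  structure(list(
    genes = genes,
    n_samples_basalt = n_samples_basalt, n_samples_soil = n_samples_soil,
    rpoa_subject_length_aa = rpoa_subject_length_aa,
    read_length_mean = read_length_mean, read_length_sd = read_length_sd,
    sequencing_depth = sequencing_depth,
    genus_labels = genus_labels,
    decoy_fraction = decoy_fraction,
    evalue_true_max = evalue_true_max,
    evalue_decoy_max = evalue_decoy_max,
    genome_equivalents = genome_equivalents,
    seed = seed
  ), class = "omics_sim_spec")
}

#' Default synthetic siderophore gene panel
#'
#' Hydroxamate (desB, desD), catecholate (entA), mixed-ligand (mbtA) and
#' carboxylate (rhbC) orthologues with planted copies per genome higher
#' on basalt than soil for the hydroxamate genes, mimicking selection for
#' desferrioxamine producers on weathering grain surfaces.
#'
#' @return Data.frame usable as the `genes` field of [omics_sim_spec()].
#' @export
default_gene_panel <- function() {
  data.frame(
    orthologue = c("desB", "desD", "entA", "mbtA", "rhbC"),
    class = c("hydroxamate", "hydroxamate", "catecholate",
              "mixed-ligand", "carboxylate"),
    subject_length_aa = c(420, 600, 250, 550, 430),
    copies_basalt = c(0.50, 0.25, 0.30, 0.10, 0.08),
    copies_soil = c(0.19, 0.045, 0.17, 0.10, 0.08),
    stringsAsFactors = FALSE
  )
}

truncnorm_lengths <- function(n, mean, sd, floor = 50) {
  if (n == 0L) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  while (any(x < floor)) {
    x[x < floor] <- stats::rnorm(sum(x < floor), mean, sd)
  }
  round(x)
}

loguniform <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Simulate homology hit tables with planted gene abundances
#'
#' In stochastic mode, the number of reads hitting orthologue g in a
#' sample is Poisson with mean G x copies(g) x 3 x slen(g) / mean read
#' length (G = genome equivalents scaled so the total expected reads
#' match the sequencing depth), read lengths are truncated-normal, and
#' expected length-normalized copies equal G x copies(g) — so
#' rpoA-normalized abundance recovers the planted copies-per-genome
#' (rpoA is planted at 1 copy/genome). In expectation mode each
#' (sample, gene, genus) emits a single aggregate row whose real-valued
#' query length encodes the exact expected full-length copies, giving a
#' machine-precision oracle.
#'
#' @param spec An `omics_sim_spec`.
#' @param expectation Emit exact expected counts instead of sampling.
#' @return Data.frame of hits (layout of [parse_hit_table()] plus
#'   `sample_id` and `substrate` columns, and `genus` when genus labels
#'   are specified).
#' @export
simulate_hit_table <- function(spec, expectation = FALSE) {
  stopifnot(inherits(spec, "omics_sim_spec"))
  set.seed(substream_seed(spec$seed, "hits"))

  samples <- data.frame(
    sample_id = c(sprintf("basalt_%02d", seq_len(spec$n_samples_basalt)),
                  sprintf("soil_%02d", seq_len(spec$n_samples_soil))),
    substrate = rep(c("basalt", "soil"),
                    c(spec$n_samples_basalt, spec$n_samples_soil)),
    stringsAsFactors = FALSE
  )

  gl <- spec$genus_labels
  if (is.null(gl)) {
    gl <- data.frame(genus = NA_character_, weight = 1,
                     desB_carriage = NA_real_, stringsAsFactors = FALSE)
  } else {
    gl$weight <- gl$weight / sum(gl$weight)
  }

  out <- lapply(seq_len(nrow(samples)), function(si) {
    substrate <- samples$substrate[si]
    genes <- spec$genes
    genes$copies <- if (substrate == "basalt") genes$copies_basalt else
      genes$copies_soil
    # rpoA: single copy per genome, the normalization anchor
    genes <- rbind(genes[c("orthologue", "subject_length_aa", "copies")],
                   data.frame(orthologue = "rpoA",
                              subject_length_aa = spec$rpoa_subject_length_aa,
                              copies = 1))

    # per-genus split: rpoA carried by every genome, desB by carriers only
    rows <- do.call(rbind, lapply(seq_len(nrow(gl)), function(gi) {
      g <- genes
      g$genus <- gl$genus[gi]
      g$copies <- g$copies * gl$weight[gi]
      if (!is.na(gl$desB_carriage[gi])) {
        g$copies[g$orthologue == "desB"] <-
          gl$weight[gi] * gl$desB_carriage[gi]
      }
      g
    }))

    if (expectation) {
      rows <- rows[rows$copies > 0, , drop = FALSE]
      expected_copies <- spec$genome_equivalents * rows$copies
      hits <- data.frame(
        read_id = sprintf("%s_exp_%03d", samples$sample_id[si],
                          seq_len(nrow(rows))),
        subject_id = rows$orthologue,
        evalue = spec$evalue_true_max,
        bitscore = 100,
        read_length_bp = expected_copies * 3 * rows$subject_length_aa,
        subject_length_aa = rows$subject_length_aa,
        stringsAsFactors = FALSE
      )
      if (!all(is.na(rows$genus))) hits$genus <- rows$genus
    } else {
      # scale genome equivalents so expected total reads = depth
      bp_per_ge <- sum(rows$copies * 3 * rows$subject_length_aa)
      ge <- spec$sequencing_depth * spec$read_length_mean / bp_per_ge
      lambda <- ge * rows$copies * 3 * rows$subject_length_aa /
        spec$read_length_mean
      n_reads <- stats::rpois(length(lambda), lambda)
      idx <- rep(seq_along(n_reads), n_reads)
      n_tot <- length(idx)
      if (n_tot == 0L) return(NULL)
      hits <- data.frame(
        read_id = sprintf("%s_r%06d", samples$sample_id[si],
                          seq_len(n_tot)),
        subject_id = rows$orthologue[idx],
        evalue = loguniform(n_tot, 1e-30, spec$evalue_true_max),
        bitscore = round(stats::runif(n_tot, 50, 300), 1),
        read_length_bp = truncnorm_lengths(n_tot, spec$read_length_mean,
                                           spec$read_length_sd),
        subject_length_aa = rows$subject_length_aa[idx],
        stringsAsFactors = FALSE
      )
      if (!all(is.na(rows$genus))) hits$genus <- rows$genus[idx]
      if (spec$decoy_fraction > 0) {
        n_decoy <- round(spec$decoy_fraction * n_tot)
        if (n_decoy > 0) {
          pick <- sample.int(n_tot, n_decoy, replace = TRUE)
          decoys <- hits[pick, , drop = FALSE]
          decoys$read_id <- sprintf("%s_decoy%06d", samples$sample_id[si],
                                    seq_len(n_decoy))
          # strictly above the analysis cutoff, below the annotation cutoff
          decoys$evalue <- loguniform(n_decoy, 1e-5 * 1.0001,
                                      spec$evalue_decoy_max)
          hits <- rbind(hits, decoys)
        }
      }
    }
    hits$sample_id <- samples$sample_id[si]
    hits$substrate <- substrate
    hits
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Specification for a synthetic dissolution experiment
#'
#' @param ligand_concentrations Ligand levels, uM (>= 0).
#' @param response_shape `"linear"` (conc = a + b c) or
#'   `"quadratic-saturating"` (conc = a + b c + d c^2, d < 0).
#' @param response_coefficients Named list per element, each a numeric
#'   vector `c(a, b)` or `c(a, b, d)` giving the *true* released
#'   concentration (uM) as a function of ligand concentration.
#' @param blank_concentrations Named numeric per element, uM, added to
#'   every true value before "measurement".
#' @param noise_sd Relative (multiplicative) measurement noise SD, >= 0.
#' @param replicates Replicates per level, >= 1.
#' @param dilution_factor ICP-MS dilution (default 5).
#' @param mass_g,volume_L,duration_h Experimental frame (0.05 g, 10 mL,
#'   90 h defaults).
#' @param seed Global seed.
#' @return Object of class `dissolution_sim_spec`.
#' @export
dissolution_sim_spec <- function(ligand_concentrations = c(0, 1, 5, 10, 20, 40),
                                 response_shape = c("linear",
                                                    "quadratic-saturating"),
                                 response_coefficients = list(
                                   Fe = c(0.5, 0.55, -0.004),
                                   Mg = c(20, 0.5, -0.003),
                                   Ca = c(15, 0.3, -0.002),
                                   Na = c(10, 0.1, -0.0005),
                                   Si = c(30, 0.4, -0.002),
                                   Al = c(0.4, 0.45, -0.003),
                                   Ti = c(0.05, 0.01, -0.00005)),
                                 blank_concentrations = NULL,
                                 noise_sd = 0.05,
                                 replicates = 4,
                                 dilution_factor = 5,
                                 mass_g = 0.05, volume_L = 0.010,
                                 duration_h = 90,
                                 seed = 1) {
  response_shape <- match.arg(response_shape)
  if (any(ligand_concentrations < 0)) {
    stop("ligand concentrations must be >= 0", call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(blank_concentrations)) {
    blank_concentrations <- stats::setNames(
      rep(0, length(response_coefficients)), names(response_coefficients))
  }
  structure(list(
    ligand_concentrations = ligand_concentrations,
    response_shape = response_shape,
    response_coefficients = response_coefficients,
    blank_concentrations = blank_concentrations,
    noise_sd = noise_sd, replicates = replicates,
    dilution_factor = dilution_factor,
    mass_g = mass_g, volume_L = volume_L, duration_h = duration_h,
    seed = seed
  ), class = "dissolution_sim_spec")
}

#' Simulate an element panel from a dissolution experiment
#'
#' Generates the tidy long-format panel consumed by
#' [dissolution_rates()]: measured (diluted) values with matched blanks,
#' such that blank-and-dilution correction recovers the true response
#' exactly in noise-free mode.
#'
#' @param spec A `dissolution_sim_spec`.
#' @param noise_free Generate on-curve values with no noise.
#' @return Data.frame with columns `sample_id, phase, ligand, ligand_uM,
#'   element, value, unit, dilution_factor, blank_value, mass_g,
#'   volume_L, duration_h` (unit `"uM"`; phase `"ligand"`).
#' @export
simulate_dissolution_panel <- function(spec, noise_free = spec$noise_sd == 0) {
  stopifnot(inherits(spec, "dissolution_sim_spec"))
  set.seed(substream_seed(spec$seed, "dissolution"))
  elements <- names(spec$response_coefficients)
  grid <- expand.grid(rep = seq_len(spec$replicates),
                      ligand_uM = spec$ligand_concentrations,
                      element = elements, stringsAsFactors = FALSE)
  true_conc <- vapply(seq_len(nrow(grid)), function(i) {
    cf <- spec$response_coefficients[[grid$element[i]]]
    cc <- grid$ligand_uM[i]
    v <- cf[1] + cf[2] * cc
    if (spec$response_shape == "quadratic-saturating" && length(cf) >= 3) {
      v <- v + cf[3] * cc^2
    }
    max(v, 0)
  }, 0)
  blank <- spec$blank_concentrations[grid$element]
  measured <- (true_conc + blank) / spec$dilution_factor
  if (!noise_free && spec$noise_sd > 0) {
    measured <- measured * (1 + stats::rnorm(length(measured), 0,
                                             spec$noise_sd))
    measured <- pmax(measured, 0)
  }
  data.frame(
    sample_id = sprintf("lig%g_rep%d", grid$ligand_uM, grid$rep),
    phase = "ligand",
    ligand = "chelator",
    ligand_uM = grid$ligand_uM,
    element = grid$element,
    value = measured,
    unit = "uM",
    dilution_factor = spec$dilution_factor,
    blank_value = unname(blank),
    mass_g = spec$mass_g,
    volume_L = spec$volume_L,
    duration_h = spec$duration_h,
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic soil incubation
#'
#' @param eddha_levels EDDHA levels, uM.
#' @param timepoints Sampling days; day 0 must be present.
#' @param replicates Replicates per treatment x level x day.
#' @param baseline Named numeric: day-0 exchangeable concentration per
#'   element, mg/kg.
#' @param soil_drift Named numeric: concentration change in plain soil
#'   over the full window, mg/kg (applies to both treatments).
#' @param basalt_effect Named numeric: extra change in soil+basalt at 0
#'   uM EDDHA over the full window, mg/kg.
#' @param eddha_slope Named numeric: additional basalt-attributable
#'   change per uM EDDHA over the full window, mg/(kg uM).
#' @param noise_sd Additive noise SD, mg/kg (one value or named per
#'   element).
#' @param seed Global seed.
#' @return Object of class `incubation_sim_spec`.
#' @details Defaults plant a 2.5-fold CDR gain at 750 uM: the EDDHA slope
#'   is `1.5 x basalt_effect / 750` per element, so the net release (and
#'   hence CO2 potential) at 750 uM is 2.5x the 0 uM value.
#' @export
incubation_sim_spec <- function(eddha_levels = c(0, 100, 425, 750),
                                timepoints = c(0, 3, 10, 20),
                                replicates = 3,
                                baseline = c(Ca = 2000, Mg = 300,
                                             Na = 30, K = 200),
                                soil_drift = c(Ca = 5, Mg = 2,
                                               Na = 0.5, K = 3),
                                basalt_effect = c(Ca = 40, Mg = 12,
                                                  Na = 2, K = 8),
                                eddha_slope = NULL,
                                noise_sd = 0,
                                seed = 1) {
  if (!0 %in% timepoints) stop("day 0 must be among the timepoints",
                               call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  elements <- names(baseline)
  if (is.null(eddha_slope)) {
    eddha_slope <- 1.5 * basalt_effect[elements] / 750
  }
  for (v in list(soil_drift, basalt_effect, eddha_slope)) {
    if (!all(elements %in% names(v))) {
      stop("soil_drift, basalt_effect and eddha_slope must cover every ",
           "baseline element", call. = FALSE)
    }
  }
  structure(list(
    eddha_levels = eddha_levels, timepoints = sort(timepoints),
    replicates = replicates, baseline = baseline,
    soil_drift = soil_drift, basalt_effect = basalt_effect,
    eddha_slope = eddha_slope, noise_sd = noise_sd, seed = seed
  ), class = "incubation_sim_spec")
}

#' Simulate a soil-microcosm incubation dataset
#'
#' Concentrations follow
#' `baseline + (day/day_max) x [soil_drift + basalt x (basalt_effect +
#' eddha_slope x level)]` plus optional additive noise, so in noise-free
#' mode the day-20 minus day-0 difference between soil+basalt and soil
#' equals `basalt_effect + eddha_slope x level` exactly, per element.
#'
#' @param spec An `incubation_sim_spec`.
#' @param noise_free Disable noise regardless of `spec$noise_sd`.
#' @return Long-format data.frame with columns `treatment, eddha_uM, day,
#'   extract, element, concentration, replicate, fe_df_preb` (extract
#'   `"ammonium-acetate"`, `fe_df_preb = FALSE`).
#' @export
simulate_incubation_dataset <- function(spec,
                                        noise_free = all(spec$noise_sd == 0)) {
  stopifnot(inherits(spec, "incubation_sim_spec"))
  set.seed(substream_seed(spec$seed, "incubation"))
  elements <- names(spec$baseline)
  day_max <- max(spec$timepoints)
  grid <- expand.grid(replicate = seq_len(spec$replicates),
                      day = spec$timepoints,
                      eddha_uM = spec$eddha_levels,
                      treatment = c("soil", "soil+basalt"),
                      element = elements,
                      stringsAsFactors = FALSE)
  frac <- grid$day / day_max
  basalt <- grid$treatment == "soil+basalt"
  conc <- spec$baseline[grid$element] +
    frac * (spec$soil_drift[grid$element] +
              basalt * (spec$basalt_effect[grid$element] +
                          spec$eddha_slope[grid$element] * grid$eddha_uM))
  if (!noise_free) {
    sd_el <- if (length(spec$noise_sd) == 1L) {
      rep(spec$noise_sd, nrow(grid))
    } else {
      spec$noise_sd[grid$element]
    }
    conc <- conc + stats::rnorm(nrow(grid), 0, sd_el)
  }
  data.frame(
    treatment = grid$treatment,
    eddha_uM = grid$eddha_uM,
    day = grid$day,
    extract = "ammonium-acetate",
    element = grid$element,
    concentration = pmax(unname(conc), 0),
    replicate = grid$replicate,
    fe_df_preb = FALSE,
    stringsAsFactors = FALSE
  )
}
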