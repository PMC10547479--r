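#' Configuration for the synthetic multi-tissue generator
#'
#' Defines the study-like conditions the generator emulates: a mixture of
#' monocyte/macrophage populations (FCN1+ monocytes, transitional,
#' homeostatic, SPP1+MAM- and SPP1+MAM+ macrophages) across several tissues,
#' with condition-dependent composition, a latent differentiation axis from
#' monocyte to the MAM+ state, planted signature genes, planted regulon
#' programs, QC-violating cells and subject-level variation.  Counts are
#' negative binomial with variance `mu + dispersion * mu^2` and a log-normal
#' per-cell library size.
#'
#' @param n_tissues number of tissues.
#' @param cells_per_tissue cells per tissue.
#' @param n_genes total genes in the shared namespace (all tissues use the
#'   same genes so cross-tissue averaging is well defined).
#' @param seed base seed; random-number streams are split per tissue and per
#'   subject so adding a tissue leaves the others untouched.
#' @param proportions named list with elements `control` and `disease`, each
#'   a probability vector over the five populations (must sum to 1).  The
#'   defaults encode a disease-expanded MAM compartment.
#' @param n_signature_genes number of planted MAM+ signature genes.
#' @param signature_log2fc log2 up-shift of signature genes in MAM+ cells.
#' @param n_ecm,n_metabolic sizes of the ECM-like and metabolic-like subsets
#'   of the planted signature (first `n_ecm` then `n_metabolic` genes).
#' @param markers_per_population size of the discrete marker block planted
#'   for each non-MAM+ population (the MAM+ identity programme is the
#'   signature itself).
#' @param marker_log2fc log2 up-shift of a population's marker block.
#' @param program_sd standard deviation of the broad per-population log2
#'   expression programme over housekeeping genes.  FCN1+ monocytes,
#'   transitional and homeostatic macrophages each carry their own
#'   programme; MAM- and MAM+ cells share a single SPP1-macrophage
#'   programme, so the two polarisation states differ only through the
#'   focused signature, markers, trajectory and regulon effects.
#' @param n_trajectory_genes genes whose expression varies linearly with the
#'   latent pseudotime, giving the differentiation axis its geometry.
#' @param trajectory_log2fc maximal absolute log2 loading of a trajectory
#'   gene over the full pseudotime range.
#' @param n_regulons number of planted regulons (the first is the MAM-driver
#'   whose activity ramps up along the MAM branch and whose targets are the
#'   first `regulon_size` signature genes; the last is a rare decoy active
#'   in ~5% of cells; the rest are bimodal decoys with their own target
#'   pool).
#' @param regulon_size target genes per regulon.
#' @param regulon_log2fc log2 up-shift of a regulon's targets at full
#'   activity.
#' @param decoy_active_frac activation probability of a decoy regulon.
#' @param dispersion negative-binomial dispersion phi (variance mu + phi
#'   mu^2).
#' @param subjects_per_condition subjects per condition within each tissue.
#' @param subject_sd standard deviation of the per-subject, per-gene random
#'   effect on the natural-log mean.
#' @param qc_violation_frac fraction of cells planted as QC violations
#'   (half high-mitochondrial, a quarter low-depth, a quarter
#'   haemoglobin-contaminated).
#' @param n_mito number of mitochondrial genes (named `MT-*`).
#' @param libsize_sdlog sdlog of the log-normal per-cell library-size factor.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   gene means.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_tissues = 6,
                       cells_per_tissue = 2000,
                       n_genes = 2000,
                       seed = 1,
                       proportions = list(
                         control = c(FCN1_mono = 0.30, transitional = 0.20,
                                     homeostatic = 0.35, MAM_neg = 0.10,
                                     MAM_pos = 0.05),
                         disease = c(FCN1_mono = 0.15, transitional = 0.20,
                                     homeostatic = 0.15, MAM_neg = 0.25,
                                     MAM_pos = 0.25)),
                       n_signature_genes = 100,
                       signature_log2fc = 1.0,
                       n_ecm = 30,
                       n_metabolic = 30,
                       markers_per_population = 30,
                       marker_log2fc = 3.0,
                       program_sd = 0.4,
                       n_trajectory_genes = 60,
                       trajectory_log2fc = 1.5,
                       n_regulons = 8,
                       regulon_size = 20,
                       regulon_log2fc = 3.0,
                       decoy_active_frac = 0.40,
                       dispersion = 0.3,
                       subjects_per_condition = 4,
                       subject_sd = 0.10,
                       qc_violation_frac = 0.05,
                       n_mito = 10,
                       libsize_sdlog = 0.3,
                       baseline_meanlog = 0.5,
                       baseline_sdlog = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  for (cond in names(cfg$proportions)) {
    p <- cfg$proportions[[cond]]
    if (abs(sum(p) - 1) > 1e-8) {
      stop("population proportions for '", cond, "' sum to ", sum(p),
           ", not 1")
    }
    if (any(p < 0)) stop("negative proportion in '", cond, "'")
    if (!identical(sort(names(p)), sort(sim_populations()))) {
      stop("proportions for '", cond, "' must be named over: ",
           paste(sim_populations(), collapse = ", "))
    }
  }
  counts <- c(cfg$n_tissues, cfg$cells_per_tissue, cfg$n_genes,
              cfg$subjects_per_condition, cfg$n_regulons, cfg$regulon_size,
              cfg$n_signature_genes)
  if (any(counts <= 0)) stop("all size parameters must be positive")
  if (!all(is.finite(c(cfg$signature_log2fc, cfg$marker_log2fc,
                       cfg$trajectory_log2fc, cfg$regulon_log2fc)))) {
    stop("effect sizes must be finite")
  }
  if (cfg$regulon_size > cfg$n_signature_genes) {
    stop("regulon_size must not exceed n_signature_genes (the driver ",
         "regulon targets signature genes)")
  }
  n_special <- cfg$n_mito + 2 + 4 * cfg$markers_per_population +
    cfg$n_signature_genes + cfg$n_trajectory_genes +
    (cfg$n_regulons - 1) * cfg$regulon_size
  if (cfg$n_genes < n_special + 50) {
    stop("n_genes = ", cfg$n_genes, " too small for the planted structure (",
         n_special, " structural genes + housekeeping)")
  }
  if (cfg$n_ecm + cfg$n_metabolic > cfg$n_signature_genes) {
    stop("ECM + metabolic subset sizes exceed the signature size")
  }
  invisible(cfg)
}

sim_populations <- function() {
  c("FCN1_mono", "transitional", "homeostatic", "MAM_neg", "MAM_pos")
}

# Pseudotime segments of the differentiation axis
# FCN1 -> transitional -> MAM- -> MAM+; homeostatic sits off-axis (NA).
sim_segments <- function() {
  list(FCN1_mono = c(0, 0.25), transitional = c(0.25, 0.50),
       MAM_neg = c(0.50, 0.75), MAM_pos = c(0.75, 1))
}

# Deterministic gene layout shared by all tissues.
sim_gene_layout <- function(cfg) {
  mito <- paste0("MT-", seq_len(cfg$n_mito))
  hb <- c("HBA", "HBB")
  idx <- cfg$n_mito + 2
  take <- function(n) {
    out <- sprintf("GENE%04d", idx + seq_len(n)); idx <<- idx + n; out
  }
  markers <- list(FCN1_mono = take(cfg$markers_per_population),
                  transitional = take(cfg$markers_per_population),
                  homeostatic = take(cfg$markers_per_population),
                  MAM_neg = take(cfg$markers_per_population))
  signature <- take(cfg$n_signature_genes)
  trajectory <- take(cfg$n_trajectory_genes)
  # driver regulon targets the leading signature genes; decoys get own pools
  regulons <- c(list(signature[seq_len(cfg$regulon_size)]),
                lapply(seq_len(cfg$n_regulons - 1),
                       function(r) take(cfg$regulon_size)))
  names(regulons) <- paste0("REG", seq_len(cfg$n_regulons))
  housekeeping <- take(cfg$n_genes - idx)
  genes <- c(mito, hb, unlist(markers, use.names = FALSE), signature,
             trajectory, unlist(regulons[-1], use.names = FALSE),
             housekeeping)
  list(genes = genes, mito = mito, hb = hb, markers = markers,
       signature = signature,
       signature_ecm = signature[seq_len(cfg$n_ecm)],
       signature_metabolic = signature[cfg$n_ecm + seq_len(cfg$n_metabolic)],
       trajectory = trajectory, regulons = regulons,
       housekeeping = housekeeping)
}

# Baseline expected counts per gene (shared across tissues for a given seed).
sim_baselines <- function(cfg, layout) {
  lam <- with_seed(substream_seed(cfg$seed, 11), {
    x <- exp(rnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog))
    names(x) <- layout$genes
    x[layout$mito] <- 8            # ~5% mitochondrial fraction in clean cells
    x[layout$hb] <- 0.05           # haemoglobin well below the 0.1% QC cutoff
    # signature and marker genes sit in the detection-sensitive expression
    # regime, where a 2-fold shift moves the detection fraction appreciably
    # (the diff.pct component of the derivation rule needs that contrast)
    x[layout$signature] <- exp(rnorm(length(layout$signature), log(0.7), 0.3))
    mk <- unlist(layout$markers, use.names = FALSE)
    x[mk] <- exp(rnorm(length(mk), log(0.8), 0.5))
    # decoy regulon targets: low baseline so activation moves them into the
    # top expression ranks (strong AUC contrast)
    decoy <- unlist(layout$regulons[-1], use.names = FALSE)
    x[decoy] <- exp(rnorm(length(decoy), log(0.5), 0.3))
    x
  })
  lam
}

# Broad per-population log2 programmes over housekeeping genes, shared
# across tissues.  MAM- and MAM+ share the SPP1-macrophage programme.
sim_programs <- function(cfg, layout) {
  rows <- c("FCN1_mono", "transitional", "homeostatic", "SPP1_mac")
  with_seed(substream_seed(cfg$seed, 13), {
    m <- matrix(rnorm(length(rows) * length(layout$housekeeping), 0,
                      cfg$program_sd),
                length(rows), length(layout$housekeeping),
                dimnames = list(rows, layout$housekeeping))
    m
  })
}

program_row <- function(population) {
  ifelse(population %in% c("MAM_neg", "MAM_pos"), "SPP1_mac", population)
}

# Trapezoid activation of a trajectory programme: full inside [lo, hi],
# cross-fading linearly over shoulders of half-width s at the segment
# boundaries, so adjacent programmes sum to 1 there and expression varies
# continuously along the differentiation axis.  The wide default shoulder
# makes the gradient span entire segments (a differentiation continuum);
# per-segment pseudotime densities peak at segment centres, so boundaries
# stay low-density and clusterable.
trap_act <- function(t, lo, hi, s = 0.10, first = FALSE, last = FALSE) {
  up <- if (first) 1 else (t - (lo - s)) / (2 * s)
  dn <- if (last) 1 else ((hi + s) - t) / (2 * s)
  pmin(1, pmax(0, pmin(up, dn)))
}

# Trajectory gene loadings (log2 per unit pseudotime), fixed per seed.
sim_traj_weights <- function(cfg, layout) {
  with_seed(substream_seed(cfg$seed, 12), {
    w <- runif(length(layout$trajectory), -1, 1) * cfg$trajectory_log2fc
    names(w) <- layout$trajectory
    w
  })
}

#' Simulate a multi-tissue single-cell cohort with known ground truth
#'
#' Generates one dataset per tissue under a shared gene namespace.  Counts
#' are negative binomial with mean `libsize x baseline x 2^(planted
#' effects) x subject effect`.  MAM+ cells up-shift the planted signature by
#' `signature_log2fc` in every tissue; the disease condition carries larger
#' MAM+/MAM- proportions than control; regulon targets co-vary with a latent
#' TF activity that ramps up along the MAM branch; designated mitochondrial
#' and haemoglobin genes are inflated in planted QC-violating cells.
#' Identical configuration and seed give bitwise-identical output.
#'
#' @param config a [sim_config()].
#' @return list with one element per tissue, each a list with `dataset` (a
#'   [ged()] whose `cell_meta$population_label` carries the true population)
#'   and `truth` (populations, pseudotime, planted gene sets, regulons with
#'   per-cell true activity, QC-violation kinds, subject assignments).
#' @export
simulate_multitissue <- function(config) {
  validate_sim_config(config)
  layout <- sim_gene_layout(config)
  lam <- sim_baselines(config, layout)
  traj_w <- sim_traj_weights(config, layout)
  programs <- sim_programs(config, layout)
  out <- lapply(seq_len(config$n_tissues), function(t) {
    simulate_tissue(config, layout, lam, traj_w, programs, tissue_index = t)
  })
  names(out) <- paste0("tissue", seq_len(config$n_tissues))
  out
}

simulate_tissue <- function(cfg, layout, lam, traj_w, programs,
                            tissue_index) {
  tissue <- paste0("tissue", tissue_index)
  n <- cfg$cells_per_tissue
  G <- cfg$n_genes
  pops <- sim_populations()
  segs <- sim_segments()

  # per-subject gene-wise random effects from per-subject streams
  n_subj <- 2 * cfg$subjects_per_condition
  subj_ids <- sprintf("%s_S%02d", tissue, seq_len(n_subj))
  subj_cond <- rep(c("control", "disease"), each = cfg$subjects_per_condition)
  subj_eff <- t(vapply(seq_len(n_subj), function(j) {
    with_seed(substream_seed(cfg$seed, 202, tissue_index, j),
              exp(rnorm(G, 0, cfg$subject_sd)))
  }, numeric(G)))

  with_seed(substream_seed(cfg$seed, 101, tissue_index), {
    subject <- rep(subj_ids, length.out = n)[sample.int(n)]
    condition <- subj_cond[match(subject, subj_ids)]
    population <- vapply(condition, function(cond) {
      sample(pops, 1, prob = cfg$proportions[[cond]][pops])
    }, character(1))

    # latent pseudotime; disease MAM- cells sit closer to the MAM+ end
    pseudotime <- rep(NA_real_, n)
    for (p in names(segs)) {
      idx <- which(population == p)
      if (!length(idx)) next
      lo <- segs[[p]][1]; wd <- diff(segs[[p]])
      u <- runif(length(idx))
      if (p == "MAM_neg") {
        # disease MAM- cells sit nearer the MAM+ end of their segment
        a <- ifelse(condition[idx] == "disease", 2.5, 1.5)
        b <- ifelse(condition[idx] == "disease", 1.5, 2.5)
        u <- stats::qbeta(u, a, b)
      } else if (p == "transitional") {
        # near-uniform: transitional cells populate both boundary corridors
        u <- stats::qbeta(u, 1.1, 1.1)
      } else {
        u <- stats::qbeta(u, 2, 2)  # concentrate at the segment centre
      }
      pseudotime[idx] <- lo + wd * u
    }

    # planted log2 effects
    E <- matrix(0, n, G, dimnames = list(NULL, layout$genes))
    E[, layout$housekeeping] <- programs[program_row(population), ,
                                         drop = FALSE]
    # homeostatic macrophages sit off the differentiation axis: discrete
    idx_h <- which(population == "homeostatic")
    if (length(idx_h)) {
      E[idx_h, layout$markers$homeostatic] <- cfg$marker_log2fc
    }
    # trajectory programmes are trapezoid functions of pseudotime: full
    # within the population's segment, cross-fading at the boundaries so
    # the differentiation axis is a continuum, not separated blobs
    on_axis <- which(!is.na(pseudotime))
    t_ax <- pseudotime[on_axis]
    E[on_axis, layout$markers$FCN1_mono] <-
      cfg$marker_log2fc * trap_act(t_ax, 0, 0.25, first = TRUE)
    E[on_axis, layout$markers$transitional] <-
      cfg$marker_log2fc * trap_act(t_ax, 0.25, 0.50)
    E[on_axis, layout$markers$MAM_neg] <-
      cfg$marker_log2fc * trap_act(t_ax, 0.50, 0.75)
    E[on_axis, layout$signature] <- E[on_axis, layout$signature] +
      cfg$signature_log2fc * trap_act(t_ax, 0.75, 1, last = TRUE)
    E[on_axis, layout$trajectory] <- E[on_axis, layout$trajectory] +
      outer(t_ax, traj_w)

    # regulon programmes: driver ramps up along the MAM branch, decoys are
    # bimodal; the last decoy is rare (exercises the retention filter)
    activity <- matrix(0, n, cfg$n_regulons,
                       dimnames = list(NULL, names(layout$regulons)))
    activity[on_axis, 1] <- pmax(0, (pseudotime[on_axis] - 0.65) / 0.35)
    if (cfg$n_regulons > 1) {
      for (r in 2:cfg$n_regulons) {
        p_on <- if (r == cfg$n_regulons) 0.05 else cfg$decoy_active_frac
        activity[, r] <- rbinom(n, 1, p_on)
      }
    }
    for (r in seq_len(cfg$n_regulons)) {
      on <- which(activity[, r] > 0)
      if (length(on)) {
        E[on, layout$regulons[[r]]] <- E[on, layout$regulons[[r]]] +
          cfg$regulon_log2fc * activity[on, r]
      }
    }

    # planted QC violations
    viol <- rep("none", n)
    n_viol <- round(cfg$qc_violation_frac * n)
    if (n_viol > 0) {
      vi <- sample.int(n, n_viol)
      kind <- sample(c("mito", "depth", "hb"), n_viol, replace = TRUE,
                     prob = c(0.5, 0.25, 0.25))
      viol[vi] <- kind
    }

    libsize <- exp(rnorm(n, 0, cfg$libsize_sdlog))
    libsize[viol == "depth"] <- libsize[viol == "depth"] * 0.05

    mu <- outer(libsize, lam) * 2^E *
      subj_eff[match(subject, subj_ids), , drop = FALSE]
    mito_cols <- match(layout$mito, layout$genes)
    hb_cols <- match(layout$hb, layout$genes)
    mu[viol == "mito", mito_cols] <- mu[viol == "mito", mito_cols] * 10
    mu[viol == "hb", hb_cols] <- mu[viol == "hb", hb_cols] * 600

    counts <- matrix(rnbinom(n * G, size = 1 / cfg$dispersion, mu = mu),
                     n, G, dimnames = list(sprintf("%s_C%05d", tissue,
                                                   seq_len(n)),
                                           layout$genes))
  })

  meta <- data.frame(tissue = tissue, subject_id = subject,
                     condition = condition, population_label = population,
                     stringsAsFactors = FALSE)
  rownames(meta) <- rownames(counts)
  regs <- lapply(names(layout$regulons), function(r) {
    gene_set(r, layout$regulons[[r]], tf = paste0("TF_", r))
  })
  names(regs) <- names(layout$regulons)
  truth <- list(
    population = population, pseudotime = pseudotime,
    signature = gene_set("MAM_pos_signature", layout$signature),
    signature_ecm = gene_set("MAM_pos_ECM", layout$signature_ecm),
    signature_metabolic = gene_set("MAM_pos_metabolic",
                                   layout$signature_metabolic),
    down_signature = gene_set("MAM_neg_signature", layout$markers$MAM_neg),
    marker_blocks = layout$markers,
    trajectory_genes = layout$trajectory,
    regulons = regs, regulon_activity = activity,
    driver_regulon = "REG1",
    qc_violation = viol, subject = subject, housekeeping = layout$housekeeping)
  list(dataset = ged(counts, meta), truth = truth)
}

#' Simulate an ageing cohort with a planted signature-score slope
#'
#' Generates a single-tissue cohort of macrophages (homeostatic, MAM- and
#' MAM+ populations) whose MAM- signature expression shifts linearly with
#' subject age at slope `age_slope` on the module-score (natural-log) scale.
#' The shifted genes are given a high baseline and low dispersion so that the
#' mean log-normalized expression tracks the log mean faithfully; a
#' subject-level random intercept (sd `subject_score_sd` on the score scale)
#' provides biological inter-subject variation.  In mouse mode a second gene
#' namespace is emitted along with the human-to-mouse ortholog table, and
#' subjects are split into young (1-3 months) and aged (21-30 months)
#' groups.
#'
#' @param config a [sim_config()] (gene layout, dispersion and library-size
#'   settings are reused; population proportions are overridden by
#'   `proportions`).
#' @param age_slope planted score change per year (human) or per month
#'   (mouse).
#' @param n_subjects number of subjects (> 0).
#' @param cells_per_subject macrophages per subject.
#' @param age_range human age range (years), sampled uniformly.
#' @param proportions population proportions of the cohort.
#' @param subject_score_sd sd of the subject-level random intercept on the
#'   score scale.
#' @param species `"human"` or `"mouse"`.
#' @param seed seed for this cohort (defaults to the config seed).
#' @return list with `dataset`, and `truth` carrying `ages`, `age_slope`,
#'   `signature` (the age-responsive MAM- gene set, always in human symbols),
#'   `subject_intercepts` and, for mouse, `ortholog_table` and `group`
#'   (young/aged).
#' @export
simulate_aging_cohort <- function(config, age_slope,
                                  n_subjects = 85,
                                  cells_per_subject = 200,
                                  age_range = c(25, 75),
                                  proportions = c(homeostatic = 0.65,
                                                  MAM_neg = 0.25,
                                                  MAM_pos = 0.10),
                                  subject_score_sd = 0.2,
                                  species = c("human", "mouse"),
                                  seed = config$seed) {
  validate_sim_config(config)
  species <- match.arg(species)
  if (n_subjects <= 0) stop("n_subjects must be positive")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  layout <- sim_gene_layout(config)
  lam <- sim_baselines(config, layout)
  sig_genes <- layout$markers$MAM_neg  # the MAM- (down) signature
  # high baseline, spread over bins: log-normalized means track the log-mean
  # shift faithfully and the genes do not collapse into a single score bin
  lam[sig_genes] <- with_seed(substream_seed(seed, 302),
                              exp(rnorm(length(sig_genes), log(40), 0.4)))
  G <- config$n_genes
  n <- n_subjects * cells_per_subject

  res <- with_seed(substream_seed(seed, 303), {
    if (species == "human") {
      ages <- runif(n_subjects, age_range[1], age_range[2])
      group <- rep(NA_character_, n_subjects)
    } else {
      group <- rep(c("young", "aged"), length.out = n_subjects)
      ages <- ifelse(group == "young", runif(n_subjects, 1, 3),
                     runif(n_subjects, 21, 30))
    }
    sex <- sample(c("F", "M"), n_subjects, replace = TRUE)
    smoking <- sample(c("never", "former", "current"), n_subjects,
                      replace = TRUE)
    u <- rnorm(n_subjects, 0, subject_score_sd)
    age_center <- mean(range(ages))

    subject <- rep(seq_len(n_subjects), each = cells_per_subject)
    population <- sample(names(proportions), n, replace = TRUE,
                         prob = proportions)
    E <- matrix(0, n, G, dimnames = list(NULL, layout$genes))
    programs <- sim_programs(config, layout)
    E[, layout$housekeeping] <- programs[program_row(population), ,
                                         drop = FALSE]
    for (p in intersect(names(layout$markers), names(proportions))) {
      idx <- which(population == p)
      if (length(idx)) E[idx, layout$markers[[p]]] <- config$marker_log2fc
    }
    idx_pos <- which(population == "MAM_pos")
    if (length(idx_pos)) {
      E[idx_pos, layout$signature] <- config$signature_log2fc
    }
    # planted ageing effect + subject intercept, natural-log scale on the
    # MAM- signature genes (converted to log2 for the shared effect matrix)
    shift_ln <- age_slope * (ages - age_center) + u
    E[, sig_genes] <- E[, sig_genes] + shift_ln[subject] / log(2)

    libsize <- exp(rnorm(n, 0, config$libsize_sdlog))
    mu <- outer(libsize, lam) * 2^E
    phi <- rep(config$dispersion, G)
    phi[match(sig_genes, layout$genes)] <- 0.05
    counts <- matrix(rnbinom(n * G, size = rep(1 / phi, each = n), mu = mu),
                     n, G,
                     dimnames = list(sprintf("AGE_C%06d", seq_len(n)),
                                     layout$genes))
    list(counts = counts, ages = ages, sex = sex, smoking = smoking,
         group = group, subject = subject, u = u, population = population)
  })

  subj_ids <- sprintf("D%03d", res$subject)
  ortho <- NULL
  sig_human <- gene_set("MAM_neg_signature", sig_genes)
  if (species == "mouse") {
    mouse_names <- mouse_symbol(layout$genes)
    ortho <- data.frame(source = layout$genes, target = mouse_names,
                        stringsAsFactors = FALSE)
    colnames(res$counts) <- mouse_names
  }
  meta <- data.frame(
    tissue = "lung", subject_id = subj_ids,
    condition = if (species == "mouse") res$group[res$subject] else "control",
    population_label = res$population,
    age = res$ages[res$subject], sex = res$sex[res$subject],
    smoking = res$smoking[res$subject], stringsAsFactors = FALSE)
  rownames(meta) <- rownames(res$counts)
  truth <- list(ages = res$ages, age_slope = age_slope,
                signature = sig_human,
                subject_intercepts = res$u, group = res$group,
                population = res$population,
                ortholog_table = ortho)
  list(dataset = ged(res$counts, meta), truth = truth)
}

# Synthetic mouse symbol for a synthetic human symbol (invertible renaming).
mouse_symbol <- function(x) {
  sub("^GENE", "Gene", sub("^MT-", "mt-", sub("^HB", "Hb", x)))
}

#' Simulate a branching differentiation manifold in embedding space
#'
#' Generates cells along a smooth one-dimensional differentiation curve in a
#' `n_dims`-dimensional embedding, with isotropic Gaussian noise and
#' overlapping class-conditional pseudotime distributions for the
#' transitional, MAM- and MAM+ states -- the geometry a diffusion map is run
#' on after data integration, where neighbouring polarisation states blend
#' into one continuous manifold rather than separate clusters.  Disease MAM-
#' cells sit closer to the MAM+ end than control MAM- cells.
#'
#' @param n_per_class cells per (class, condition) combination; MAM- cells
#'   are generated once per condition, transitional and MAM+ once each.
#' @param n_dims embedding dimensionality.
#' @param curve_length length of the curve in noise-SD units (larger =
#'   better separated ends).
#' @param noise isotropic noise standard deviation.
#' @param t_sd spread of each class's pseudotime distribution.
#' @param disease_shift how much the disease MAM- pseudotime centre moves
#'   toward the MAM+ end.
#' @param seed RNG seed.
#' @return list with `embedding` (cells x n_dims), `labels`
#'   (transitional/MAM_neg/MAM_pos), `condition` (control/disease for MAM-
#'   cells, `NA` otherwise) and `pseudotime`.
#' @export
simulate_branching_embedding <- function(n_per_class = 500, n_dims = 50,
                                         curve_length = 14, noise = 1,
                                         t_sd = 0.10, disease_shift = 0.12,
                                         seed = 1) {
  with_seed(seed, {
    centre <- c(transitional = 0.22, MAM_neg_control = 0.46,
                MAM_neg_disease = 0.46 + disease_shift, MAM_pos = 0.78)
    counts <- c(n_per_class, n_per_class, n_per_class, n_per_class)
    t <- unlist(lapply(seq_along(centre), function(i) {
      pmin(1, pmax(0, rnorm(counts[i], centre[i], t_sd)))
    }))
    labels <- rep(c("transitional", "MAM_neg", "MAM_neg", "MAM_pos"), counts)
    condition <- rep(c(NA, "control", "disease", NA), counts)
    # smooth curve through embedding space: two orthogonal harmonics
    emb <- matrix(rnorm(length(t) * n_dims, 0, noise), length(t), n_dims)
    emb[, 1] <- emb[, 1] + curve_length * noise * t
    emb[, 2] <- emb[, 2] + 0.35 * curve_length * noise * sin(pi * t)
    rownames(emb) <- sprintf("BR_C%05d", seq_along(t))
    list(embedding = emb, labels = labels, condition = condition,
         pseudotime = t)
  })
}
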