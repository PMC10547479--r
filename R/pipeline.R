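#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the published
#' analysis constants (QC bounds 300/5000 genes, 20% mitochondrial and 0.1%
#' haemoglobin cutoffs; resolution scan 0.20-1.00 in steps of 0.05 with a
#' 0.30 floor; pseudo-bulk merge threshold r = 0.6; signature cutoffs 0.5 /
#' 1.96; diffusion settings of 50 PCs, k = 10% and a 25,000-cell
#' downsample; regulon retention 10% in 4 tissues and DOR pseudocount 0.05;
#' 10-cell donor minimum) plus the synthetic-cohort size and the output
#' location.  Validated on construction and round-trips through
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed global seed, fanned out to per-stage substreams.
#' @param out_dir output directory.
#' @param stages stages to run, in dependency order.
#' @param n_tissues,cells_per_tissue,n_genes synthetic cohort size.
#' @param min_genes,max_genes,max_mito,max_hb QC parameters.
#' @param resolutions,min_resolution,k_neighbors clustering parameters.
#' @param r_threshold pseudo-bulk merge correlation threshold.
#' @param lfc_thresh,z_thresh signature derivation cutoffs.
#' @param n_pcs_diffusion,k_frac,downsample_target propensity parameters.
#' @param top_fraction,retention_min_frac,retention_min_tissues,dor_pseudocount
#'   regulon parameters.
#' @param aging_n_subjects,aging_cells_per_subject,aging_slope,min_cells_donor
#'   ageing-stage parameters.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            out_dir = tempfile("mamscope_run_"),
                            stages = c("simulate", "qc", "cluster",
                                       "signature", "propensity", "regulons",
                                       "aging"),
                            n_tissues = 3, cells_per_tissue = 400,
                            n_genes = 600,
                            min_genes = 300, max_genes = 5000,
                            max_mito = 0.20, max_hb = 0.001,
                            resolutions = seq(0.20, 1.00, by = 0.05),
                            min_resolution = 0.30, k_neighbors = 20,
                            r_threshold = 0.6,
                            lfc_thresh = 0.5, z_thresh = 1.96,
                            n_pcs_diffusion = 50, k_frac = 0.10,
                            downsample_target = 25000,
                            top_fraction = 0.05,
                            retention_min_frac = 0.10,
                            retention_min_tissues = 4,
                            dor_pseudocount = 0.05,
                            aging_n_subjects = 40,
                            aging_cells_per_subject = 60,
                            aging_slope = 0.02,
                            min_cells_donor = 10) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid pipeline config: ", msg)
  chk(cfg$min_genes >= 0 && cfg$max_genes > cfg$min_genes,
      "gene-count bounds")
  chk(cfg$max_mito > 0 && cfg$max_mito <= 1, "max_mito must be in (0, 1]")
  chk(cfg$max_hb > 0 && cfg$max_hb <= 1, "max_hb must be in (0, 1]")
  chk(abs(cfg$r_threshold) <= 1, "r_threshold must be a correlation in [-1, 1]")
  chk(all(cfg$resolutions > 0), "resolutions must be positive")
  chk(cfg$top_fraction > 0 && cfg$top_fraction <= 1,
      "top_fraction must be in (0, 1]")
  chk(cfg$k_frac > 0 && cfg$k_frac <= 1, "k_frac must be in (0, 1]")
  chk(cfg$retention_min_frac >= 0 && cfg$retention_min_frac <= 1,
      "retention_min_frac must be in [0, 1]")
  chk(cfg$dor_pseudocount > 0, "dor_pseudocount must be positive")
  chk(cfg$min_cells_donor >= 1, "min_cells_donor must be >= 1")
  known <- c("simulate", "qc", "cluster", "signature", "propensity",
             "regulons", "aging")
  chk(all(cfg$stages %in% known), paste("unknown stage; known:",
                                        paste(known, collapse = ", ")))
  invisible(cfg)
}

#' Write / read a pipeline configuration as flat key = value text
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `path` (write) or the re-validated config (read).
#' @export
write_pipeline_config <- function(config, path) {
  ser <- vapply(names(config), function(k) {
    paste(k, paste(config[[k]], collapse = ","), sep = " = ")
  }, character(1))
  writeLines(ser, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  defaults <- pipeline_config()
  cfg <- defaults
  for (item in kv) {
    k <- item[1]; v <- strsplit(item[2], ",", fixed = TRUE)[[1]]
    if (!k %in% names(defaults)) next
    proto <- defaults[[k]]
    cfg[[k]] <- if (is.numeric(proto)) as.numeric(v) else v
  }
  for (k in c("seed", "n_tissues", "cells_per_tissue", "n_genes",
              "k_neighbors", "aging_n_subjects", "aging_cells_per_subject",
              "min_cells_donor")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Adjusted Rand index between two labellings
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (1 for identical partitions, ~0 for
#'   independent ones).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) {
    # degenerate partitions (e.g. all singletons): 1 iff identical
    same <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
    return(as.numeric(same))
  }
  (sum_ij - expected) / (maxi - expected)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order on a synthetic
#' multi-tissue cohort, writing every stage output under `config$out_dir`
#' and returning a manifest of output files with MD5 content hashes.
#' Identical configuration and seed produce identical hashes.  A failing
#' stage halts the run with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (data.frame: stage, file, md5), `summary`
#'   (named list of headline numbers) and `out_dir`, invisibly also written
#'   as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0))
  summary <- list()
  root <- normalizePath(config$out_dir)
  record <- function(stage, paths) {
    rel <- sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", root),
                      "/?"), "", normalizePath(unlist(paths)))
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, file = rel,
                                  md5 = unname(tools::md5sum(
                                    normalizePath(unlist(paths))))))
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sims <- NULL; tissues <- NULL; embeddings <- NULL; merged_labels <- NULL
  stats <- NULL; sig_up <- NULL; sig_dn <- NULL

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      scfg <- sim_config(n_tissues = config$n_tissues,
                         cells_per_tissue = config$cells_per_tissue,
                         n_genes = config$n_genes, seed = config$seed)
      sims <<- simulate_multitissue(scfg)
      paths <- character(0)
      for (nm in names(sims)) {
        p <- write_dataset(sims[[nm]]$dataset,
                           file.path(config$out_dir, nm))
        paths <- c(paths, p)
      }
      gmt <- file.path(config$out_dir, "true_regulons.gmt")
      write_gene_sets(sims[[1]]$truth$regulons, gmt)
      sig <- file.path(config$out_dir, "true_signature.gmt")
      write_gene_sets(list(sims[[1]]$truth$signature,
                           sims[[1]]$truth$down_signature), sig)
      record("simulate", c(paths, gmt, sig))
    })
  }
  if (is.null(sims)) stop("pipeline requires the simulate stage or inputs")

  if ("qc" %in% config$stages) {
    run_stage("qc", function() {
      before <- vapply(sims, function(s) n_cells(s$dataset), numeric(1))
      filtered <- lapply(sims, function(s) {
        keep <- apply_qc(s$dataset, min_genes = config$min_genes,
                         max_genes = config$max_genes,
                         max_mito = config$max_mito, max_hb = config$max_hb)
        idx <- match(cell_ids(keep), cell_ids(s$dataset))
        list(dataset = keep, truth = s$truth, cell_index = idx)
      })
      ds <- filter_shared_genes(lapply(filtered, `[[`, "dataset"))
      for (i in seq_along(filtered)) filtered[[i]]$dataset <- ds[[i]]
      sims <<- filtered
      tab <- data.frame(tissue = names(sims), cells_before = before,
                        cells_after = vapply(sims, function(s)
                          n_cells(s$dataset), numeric(1)))
      p <- write_tsv(tab, file.path(config$out_dir, "qc_summary.tsv"))
      record("qc", p)
      summary$qc_cells_kept <<- sum(tab$cells_after)
    })
  }

  tissues <- lapply(sims, function(s) log_normalize(s$dataset))

  if ("cluster" %in% config$stages) {
    run_stage("cluster", function() {
      embeddings <<- list(); merged_labels <<- list()
      aris <- numeric(0)
      paths <- character(0)
      for (nm in names(tissues)) {
        emb <- embed_cells(tissues[[nm]])
        sel <- select_resolution(emb, resolutions = config$resolutions,
                                 min_resolution = config$min_resolution,
                                 k_neighbors = config$k_neighbors,
                                 seed = substream_seed(config$seed, 21))
        mg <- merge_clusters(emb, sel$labels,
                             r_threshold = config$r_threshold)
        embeddings[[nm]] <<- emb
        merged_labels[[nm]] <<- mg$labels
        truth_pop <- tissues[[nm]]$cell_meta$population_label
        aris <- c(aris, adjusted_rand_index(mg$labels, truth_pop))
        p1 <- write_tsv(data.frame(cell_id = cell_ids(tissues[[nm]]),
                                   cluster = mg$labels),
                        file.path(config$out_dir,
                                  paste0(nm, "_clusters.tsv")))
        p2 <- write_tsv(sel$silhouette_table,
                        file.path(config$out_dir,
                                  paste0(nm, "_silhouette.tsv")))
        p3 <- file.path(config$out_dir, paste0(nm, "_merge_history.json"))
        jsonlite::write_json(mg$history, p3, digits = NA)
        paths <- c(paths, p1, p2, p3)
      }
      record("cluster", paths)
      summary$cluster_ari <<- mean(aris)
    })
  }

  pop_of <- function(d) d$cell_meta$population_label

  if ("signature" %in% config$stages) {
    run_stage("signature", function() {
      stats <<- differential_stats(
        tissues,
        lapply(tissues, function(d) pop_of(d) == "MAM_pos"),
        lapply(tissues, function(d) pop_of(d) == "MAM_neg"))
      sig_up <<- derive_cross_tissue_signature(
        stats, lfc_thresh = config$lfc_thresh, z_thresh = config$z_thresh,
        direction = "up", name = "MAM_pos_signature")
      sig_dn <<- suppressWarnings(derive_cross_tissue_signature(
        stats, lfc_thresh = config$lfc_thresh, z_thresh = config$z_thresh,
        direction = "down", name = "MAM_neg_signature"))
      p1 <- write_tsv(stats$summary,
                      file.path(config$out_dir, "differential_stats.tsv"))
      p2 <- file.path(config$out_dir, "signatures.gmt")
      sets <- Filter(function(s) length(s$genes) > 0, list(sig_up, sig_dn))
      if (length(sets)) write_gene_sets(sets, p2) else writeLines(character(0), p2)
      record("signature", c(p1, p2))
      truth_sig <- sims[[1]]$truth$signature$genes
      summary$signature_size <<- length(sig_up$genes)
      summary$signature_recall <<-
        length(intersect(sig_up$genes, truth_sig)) / length(truth_sig)
      summary$signature_false_positives <<-
        length(setdiff(sig_up$genes, truth_sig))
    })
  }

  if ("propensity" %in% config$stages) {
    run_stage("propensity", function() {
      if (is.null(embeddings)) stop("cluster stage required first")
      paths <- character(0)
      all_p <- list()
      for (nm in names(tissues)) {
        d <- tissues[[nm]]
        traj <- pop_of(d) %in% c("transitional", "MAM_neg", "MAM_pos")
        sub <- subset_ged(d, cells = which(traj))
        sub <- downsample_cells(sub, target = config$downsample_target,
                                seed = substream_seed(config$seed, 31))
        emb <- embed_cells(sub, n_pcs = config$n_pcs_diffusion)
        model <- transition_matrix(emb, n_pcs = config$n_pcs_diffusion,
                                   k_frac = config$k_frac)
        res <- propensity_scores(model, pop_of(sub))
        cond <- sub$cell_meta$condition[pop_of(sub) == "MAM_neg"]
        cmp <- compare_conditions(res, cond)
        res$condition <- cond
        res$tissue <- nm
        all_p[[nm]] <- res
        paths <- c(paths,
                   write_tsv(res, file.path(config$out_dir,
                                            paste0(nm, "_propensity.tsv"))),
                   write_tsv(cmp, file.path(config$out_dir,
                                            paste0(nm,
                                                   "_propensity_tests.tsv"))))
      }
      record("propensity", paths)
      pooled <- do.call(rbind, all_p)
      ok <- !is.na(pooled$score)
      summary$propensity_median_disease <<-
        median(pooled$score[ok & pooled$condition == "disease"])
      summary$propensity_median_control <<-
        median(pooled$score[ok & pooled$condition == "control"])
    })
  }

  if ("regulons" %in% config$stages) {
    run_stage("regulons", function() {
      regs <- sims[[1]]$truth$regulons
      active_list <- list(); labels_list <- list()
      auc_store <- list()
      for (nm in names(tissues)) {
        act <- aucell_score(tissues[[nm]], regs,
                            top_fraction = config$top_fraction,
                            seed = substream_seed(config$seed, 41))
        act <- binarize_all(act)
        active_list[[nm]] <- act$active
        labels_list[[nm]] <- pop_of(tissues[[nm]])
        auc_store[[nm]] <- act$auc
      }
      kept <- retention_filter(active_list,
                               min_frac = config$retention_min_frac,
                               min_tissues = config$retention_min_tissues)
      dor <- compute_dor(lapply(active_list, function(a)
                           a[, kept, drop = FALSE]),
                         labels_list, pseudocount = config$dor_pseudocount)
      spec <- if (!is.null(stats) && length(sig_up$genes)) {
        lfc <- setNames(stats$summary$mean_log2FC, stats$summary$gene)
        vapply(kept, function(r) {
          regulon_specificity(regs[[r]], sig_up, sig_dn, lfc,
                              universe = stats$summary$gene)
        }, numeric(1))
      } else setNames(rep(NA_real_, length(kept)), kept)
      tab <- data.frame(regulon = kept,
                        median_dor = dor$median_dor[kept],
                        specificity = spec[kept])
      tab <- tab[order(-tab$median_dor), ]
      p <- write_tsv(tab, file.path(config$out_dir,
                                    "regulon_priority.tsv"))
      record("regulons", p)
      summary$regulons_retained <<- length(kept)
      summary$top_regulon <<- tab$regulon[1]
    })
  }

  if ("aging" %in% config$stages) {
    run_stage("aging", function() {
      scfg <- sim_config(n_tissues = 1, cells_per_tissue = 100,
                         n_genes = config$n_genes, seed = config$seed)
      cohort <- simulate_aging_cohort(
        scfg, age_slope = config$aging_slope,
        n_subjects = config$aging_n_subjects,
        cells_per_subject = config$aging_cells_per_subject,
        seed = substream_seed(config$seed, 51))
      d <- log_normalize(cohort$dataset)
      tab <- pseudobulk_scores(d, cohort$truth$signature,
                               min_cells = config$min_cells_donor,
                               seed = substream_seed(config$seed, 52))
      reg <- covariate_regression(
        tab, paste0("score_", cohort$truth$signature$name))
      p1 <- write_tsv(tab, file.path(config$out_dir, "subject_scores.tsv"))
      p2 <- write_tsv(reg, file.path(config$out_dir,
                                     "aging_regression.tsv"))
      record("aging", c(p1, p2))
      est <- reg[reg$term == "age", ]
      summary$aging_slope_estimate <<- est$estimate
      summary$aging_slope_p <<- est$p
    })
  }

  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(list(manifest = manifest, summary = summary), mp,
                       auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, summary = summary, out_dir = config$out_dir)
}
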