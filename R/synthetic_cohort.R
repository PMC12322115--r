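# Synthetic longitudinal cohort with planted ground truth. Every downstream
# stage of the pipeline is testable against the labels planted here.

#' Simulation parameters for a synthetic longitudinal cohort
#'
#' Defaults emulate a refractory lung-cancer PDC cohort: ~30 patients
#' sampled at 2 timepoints, targeted sequencing at ~200x depth, a 48-drug
#' screen, bulk transcriptomes that are Dirichlet mixtures of 7
#' drug-tolerant cell-type profiles, exponential survival with a planted
#' hazard ratio of 2, and Hill-model dose-response grids.
#'
#' @param n_patients number of patients.
#' @param n_timepoints timepoints per patient (2-4).
#' @param classes planted evolution class per patient for the focal gene
#'   (recycled over patients); each of `"persistence"`, `"extinction"`,
#'   `"expansion"`, `"absent"`.
#' @param focal_gene gene whose truncal dynamics define the classes.
#' @param depth_mean mean sequencing depth (reads) per variant site.
#' @param vaf_truncal,vaf_private Beta(a, b) shape pairs for truncal and
#'   private (passenger) VAFs.
#' @param passengers_per_sample Poisson mean of private passenger variants
#'   per sample.
#' @param n_drugs drugs in the screen.
#' @param n_sensitive drugs with a planted sensitivity shift in the target
#'   (extinction) group.
#' @param delta planted log2 AUC shift at later timepoints for sensitive
#'   drugs in the target group (negative = sensitization).
#' @param sigma_auc log2-scale AUC noise SD.
#' @param n_genes genes in the bulk expression matrix.
#' @param n_informative planted response-driving genes per signature drug.
#' @param n_sig_drugs drugs whose AUC carries an expression-driven
#'   component.
#' @param n_celltypes reference cell types for deconvolution.
#' @param dirichlet_conc Dirichlet concentration of mixing fractions.
#' @param expr_noise bulk expression noise SD, as a fraction of the mean
#'   mixed signal.
#' @param hazard_beta planted log hazard ratio per unit score.
#' @param hill `list(m = , Dm = )` median-effect parameters for simulated
#'   dose-response grids.
#' @param synergy_offset additive inhibition excess planted on combination
#'   wells (0 = Loewe-additive).
#' @param presence presence rule used to guarantee read-level presence of
#'   planted-present variants (alt counts are resampled until they pass, so
#'   stochastic presence failures cannot confound classification tests).
#' @return list classed `lp_sim_params`.
#' @export
sim_params <- function(n_patients = 30L,
                       n_timepoints = 2L,
                       classes = c("persistence", "extinction", "expansion"),
                       focal_gene = "EGFR",
                       depth_mean = 200,
                       vaf_truncal = c(8, 12),
                       vaf_private = c(2, 8),
                       passengers_per_sample = 5,
                       n_drugs = 48L,
                       n_sensitive = 8L,
                       delta = -0.5,
                       sigma_auc = 0.1,
                       n_genes = 200L,
                       n_informative = 10L,
                       n_sig_drugs = 2L,
                       n_celltypes = 7L,
                       dirichlet_conc = 1,
                       expr_noise = 0.05,
                       hazard_beta = log(2),
                       hill = list(m = 2, Dm = 10),
                       synergy_offset = 0.1,
                       presence = presence_rule()) {
  p <- as.list(environment())
  if (p$n_timepoints < 2 || p$n_timepoints > 4) {
    stop("n_timepoints must be between 2 and 4")
  }
  stopifnot(p$n_patients >= 1, p$depth_mean > 0,
            all(p$vaf_truncal > 0), all(p$vaf_private > 0),
            p$n_drugs >= 1, p$n_sensitive <= p$n_drugs,
            p$sigma_auc >= 0, p$n_genes >= 1,
            p$n_informative <= p$n_genes, p$n_celltypes >= 2,
            p$dirichlet_conc > 0, p$expr_noise >= 0,
            p$hill$m > 0, p$hill$Dm > 0)
  bad <- setdiff(p$classes, c("persistence", "extinction", "expansion", "absent"))
  if (length(bad)) stop("unknown evolution class: ", bad[1])
  structure(p, class = "lp_sim_params")
}

# Draw (ref, alt) read counts for a variant that must pass the presence
# rule: resample until alt >= min_alt and alt/depth >= min_vaf.
draw_present_counts <- function(vaf, depth_mean, rule) {
  repeat {
    depth <- max(stats::rpois(1, depth_mean), rule$min_alt)
    alt <- stats::rbinom(1, depth, vaf)
    if (alt >= rule$min_alt && alt / depth >= rule$min_vaf) {
      return(c(ref = depth - alt, alt = alt))
    }
  }
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[1] <- 1
  g / sum(g)
}

CELLTYPE_NAMES <- c("E_Ctrl", "E_AZD", "E_XAV", "L_AZD", "L_XAV",
                    "L_Combi", "L_Multi")

#' Generate a synthetic longitudinal cohort with planted ground truth
#'
#' Produces a coherent bundle: a variant table whose focal-gene dynamics
#' realize the planted evolution classes (with read-level presence
#' guaranteed by resampling), a drug AUC matrix with a planted group x
#' time sensitivity shift, bulk expression as Dirichlet mixtures of
#' log-normal cell-type profiles (with an expression-driven AUC component
#' on designated drugs), an exponential survival table with a planted
#' hazard, and Hill-model dose-response grids with a controllable
#' synergy offset. Deterministic given `params` and `seed`.
#'
#' @param params [sim_params()].
#' @param seed integer seed.
#' @return list classed `lp_cohort` with elements `variants`,
#'   `sample_info`, `fusions` (patient -> timepoint -> fusion names),
#'   `auc`, `expression`, `reference_profiles`, `survival`, `dose_grids`
#'   and `truth` (planted labels: `evolution_class`, `target_group`,
#'   `sensitive_drugs`, `signature_drugs`, `informative_genes`,
#'   `fractions`, `hazard_beta`, `synergy_offset`).
#' @export
generate_cohort <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "lp_sim_params"))
  set.seed(as.integer(seed))
  p <- params
  patients <- sprintf("P%03d", seq_len(p$n_patients))
  classes <- rep(p$classes, length.out = p$n_patients)
  names(classes) <- patients
  tps <- seq_len(p$n_timepoints)
  if ("expansion" %in% classes && p$n_timepoints < 2) {
    stop("expansion class requires at least 2 timepoints")
  }
  sample_info <- do.call(rbind, lapply(patients, function(pt) {
    data.frame(sample_id = sprintf("%s_T%d", pt, tps), patient_id = pt,
               timepoint = tps, stringsAsFactors = FALSE)
  }))

  ## (a) variants ------------------------------------------------------
  rows <- list()
  add_row <- function(pt, tp, gene, pchg, vaf_shape) {
    vaf <- stats::rbeta(1, vaf_shape[1], vaf_shape[2])
    rc <- draw_present_counts(vaf, p$depth_mean, p$presence)
    rows[[length(rows) + 1]] <<- data.frame(
      patient_id = pt, sample_id = sprintf("%s_T%d", pt, tp),
      timepoint = tp, gene = gene, protein_change = pchg,
      ref_count = unname(rc["ref"]), alt_count = unname(rc["alt"]),
      stringsAsFactors = FALSE)
  }
  for (pt in patients) {
    cls <- classes[[pt]]
    for (tp in tps) {
      # focal-gene truncal variant(s) realizing the planted class
      if (cls == "persistence") {
        add_row(pt, tp, p$focal_gene, "L858R", p$vaf_truncal)
      } else if (cls == "extinction") {
        if (tp == 1) add_row(pt, tp, p$focal_gene, "L858R", p$vaf_truncal)
      } else if (cls == "expansion") {
        add_row(pt, tp, p$focal_gene, "L858R", p$vaf_truncal)
        if (tp >= 2) add_row(pt, tp, p$focal_gene, "I744M", p$vaf_truncal)
      }
      # private passenger variants, unique per sample
      n_pass <- stats::rpois(1, p$passengers_per_sample)
      if (n_pass > 0) {
        genes <- sprintf("PSG%03d", sample.int(300, n_pass, replace = FALSE))
        for (j in seq_len(n_pass)) {
          add_row(pt, tp, genes[j], sprintf("V%d_%s_T%d", j, pt, tp),
                  p$vaf_private)
        }
      }
    }
  }
  variants <- variant_table(do.call(rbind, rows))

  ## fusions: survive to the next timepoint w.p. 0.5, Poisson new arrivals
  fusion_pool <- sprintf("FUS%02d--PRT%02d", 1:40, 40:1)
  fusions <- lapply(patients, function(pt) {
    sets <- list()
    cur <- sample(fusion_pool, stats::rpois(1, 2))
    sets[["1"]] <- cur
    for (tp in tps[-1]) {
      kept <- cur[stats::runif(length(cur)) < 0.5]
      new <- sample(setdiff(fusion_pool, kept), stats::rpois(1, 1))
      cur <- union(kept, new)
      sets[[as.character(tp)]] <- cur
    }
    sets
  })
  names(fusions) <- patients

  ## (c) expression: Dirichlet mixtures of log-normal cell-type profiles
  genes <- sprintf("G%04d", seq_len(p$n_genes))
  celltypes <- if (p$n_celltypes <= length(CELLTYPE_NAMES)) {
    CELLTYPE_NAMES[seq_len(p$n_celltypes)]
  } else sprintf("CT%02d", seq_len(p$n_celltypes))
  ref <- matrix(stats::rlnorm(p$n_celltypes * p$n_genes, meanlog = 2,
                              sdlog = 1),
                nrow = p$n_celltypes, dimnames = list(celltypes, genes))
  fractions <- t(vapply(sample_info$sample_id, function(s) {
    rdirichlet1(rep(p$dirichlet_conc, p$n_celltypes))
  }, numeric(p$n_celltypes)))
  colnames(fractions) <- celltypes
  signal <- fractions %*% ref                       # samples x genes
  noise_sd <- p$expr_noise * mean(signal)
  expr <- t(pmax(signal + matrix(stats::rnorm(length(signal), 0, noise_sd),
                                 nrow = nrow(signal)), 0))
  dimnames(expr) <- list(genes, sample_info$sample_id)

  ## (b) drug AUC with planted group x time shift + expression component
  drugs <- sprintf("drug%02d", seq_len(p$n_drugs))
  sensitive_drugs <- drugs[seq_len(p$n_sensitive)]
  sig_drugs <- if (p$n_sig_drugs > 0) {
    drugs[p$n_drugs - seq_len(p$n_sig_drugs) + 1]
  } else character(0)
  target_group <- patients[classes == "extinction"]
  baseline <- stats::runif(p$n_drugs, 0.4, 0.7)
  names(baseline) <- drugs
  informative <- lapply(sig_drugs, function(d) {
    sample(genes, p$n_informative)
  })
  names(informative) <- sig_drugs
  w_list <- lapply(sig_drugs, function(d) {
    stats::runif(p$n_informative, 0.5, 1) * sample(c(-1, 1), p$n_informative,
                                                   replace = TRUE)
  })
  names(w_list) <- sig_drugs
  expr_z <- t(scale(t(expr)))
  expr_z[is.na(expr_z)] <- 0
  log2auc <- matrix(rep(log2(baseline), each = nrow(sample_info)),
                    nrow = nrow(sample_info),
                    dimnames = list(sample_info$sample_id, drugs))
  later <- sample_info$timepoint >= 2
  in_group <- sample_info$patient_id %in% target_group
  for (d in sensitive_drugs) {
    log2auc[later & in_group, d] <- log2auc[later & in_group, d] + p$delta
  }
  for (d in sig_drugs) {
    contrib <- drop(crossprod(expr_z[informative[[d]], , drop = FALSE],
                              w_list[[d]]))
    contrib <- contrib / max(stats::sd(contrib), 1e-12) * 0.15
    log2auc[, d] <- log2auc[, d] + contrib
  }
  log2auc <- log2auc + matrix(stats::rnorm(length(log2auc), 0, p$sigma_auc),
                              nrow = nrow(log2auc))
  auc <- pmin(pmax(2^log2auc, 1e-4), 1)

  ## (d) survival: exponential hazard on a per-patient score
  score <- stats::rnorm(p$n_patients)
  names(score) <- patients
  rate <- 0.02 * exp(p$hazard_beta * score)
  ev_time <- stats::rexp(p$n_patients, rate)
  cens <- stats::rexp(p$n_patients, 0.01)
  surv <- data.frame(patient_id = patients,
                     time_months = pmin(ev_time, cens),
                     event = as.integer(ev_time <= cens),
                     score = score, stringsAsFactors = FALSE)

  ## (e) dose-response grids
  doses <- p$hill$Dm * 2^seq(-2, 2)
  dose_grids <- list(
    synergy  = simulate_dose_grid(doses, doses, m_a = p$hill$m,
                                  Dm_a = p$hill$Dm, m_b = p$hill$m,
                                  Dm_b = p$hill$Dm,
                                  offset = p$synergy_offset),
    additive = simulate_dose_grid(doses, doses, m_a = p$hill$m,
                                  Dm_a = p$hill$Dm, m_b = p$hill$m,
                                  Dm_b = p$hill$Dm, offset = 0))

  structure(list(
    variants = variants, sample_info = sample_info, fusions = fusions,
    auc = auc, expression = expr, reference_profiles = ref,
    survival = surv, dose_grids = dose_grids,
    truth = list(evolution_class = classes, target_group = target_group,
                 sensitive_drugs = sensitive_drugs,
                 signature_drugs = sig_drugs,
                 informative_genes = informative,
                 fractions = fractions, hazard_beta = p$hazard_beta,
                 synergy_offset = p$synergy_offset),
    params = p, seed = as.integer(seed)), class = "lp_cohort")
}

#' @export
print.lp_cohort <- function(x, ...) {
  cat("Synthetic longitudinal cohort\n")
  cat(sprintf("  %d patients x %d timepoints (%d samples), %d variant rows\n",
              x$params$n_patients, x$params$n_timepoints,
              nrow(x$sample_info), nrow(x$variants)))
  cat(sprintf("  %d drugs (%d shift-sensitive, %d expression-driven), %d genes, %d cell types\n",
              ncol(x$auc), length(x$truth$sensitive_drugs),
              length(x$truth$signature_drugs), nrow(x$expression),
              nrow(x$reference_profiles)))
  cat(sprintf("  planted classes: %s\n",
              paste(names(table(x$truth$evolution_class)),
                    table(x$truth$evolution_class), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a cohort bundle to a directory of plain-text files
#' @param bundle an `lp_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(bundle$variants, file.path(dir, "variants.tsv"))
  utils::write.table(bundle$sample_info, file.path(dir, "sample_info.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fus <- do.call(rbind, lapply(names(bundle$fusions), function(pt) {
    do.call(rbind, lapply(names(bundle$fusions[[pt]]), function(tp) {
      f <- bundle$fusions[[pt]][[tp]]
      if (length(f) == 0) return(NULL)
      data.frame(sample_id = sprintf("%s_T%s", pt, tp), fusion_name = f,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(fus)) fus <- data.frame(sample_id = character(0),
                                      fusion_name = character(0))
  utils::write.table(fus, file.path(dir, "fusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(bundle$auc, file.path(dir, "auc.tsv"), "sample_id")
  write_matrix_tsv(bundle$expression, file.path(dir, "expression.tsv"), "gene")
  write_matrix_tsv(bundle$reference_profiles,
                   file.path(dir, "reference_profiles.tsv"), "celltype")
  utils::write.table(bundle$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(evolution_class = as.list(bundle$truth$evolution_class),
         target_group = bundle$truth$target_group,
         sensitive_drugs = bundle$truth$sensitive_drugs,
         signature_drugs = bundle$truth$signature_drugs,
         informative_genes = bundle$truth$informative_genes,
         hazard_beta = bundle$truth$hazard_beta,
         synergy_offset = bundle$truth$synergy_offset),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate expression with a planted sparse linear drug-response signal
#'
#' Generates a log-normal genes x samples expression matrix and a drug AUC
#' vector driven by a sparse linear combination of `n_informative` genes
#' (on the per-gene z-score scale, matching the standardization the
#' learner applies), plus Gaussian noise — the substrate for
#' signature-recovery experiments.
#'
#' @param n_samples,n_genes matrix dimensions.
#' @param n_informative planted response-driving genes.
#' @param signal_sd SD of the expression-driven AUC component.
#' @param noise_sd SD of the residual AUC noise.
#' @param seed integer seed.
#' @return list `expression` (genes x samples), `auc` (named numeric per
#'   sample, in \[0.01, 0.99\]), `informative` (gene names), `weights`.
#' @export
simulate_signature_data <- function(n_samples = 500L, n_genes = 2000L,
                                    n_informative = 20L, signal_sd = 0.15,
                                    noise_sd = 0.05, seed = 1L) {
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- sprintf("S%04d", seq_len(n_samples))
  expr <- matrix(stats::rlnorm(n_genes * n_samples, meanlog = 2, sdlog = 0.5),
                 nrow = n_genes, dimnames = list(genes, samples))
  informative <- sample(genes, n_informative)
  w <- stats::runif(n_informative, 0.5, 1) *
    sample(c(-1, 1), n_informative, replace = TRUE)
  z <- t(scale(t(expr[informative, , drop = FALSE])))
  y <- drop(crossprod(z, w))
  y <- y / stats::sd(y) * signal_sd
  auc <- pmin(pmax(0.5 + y + stats::rnorm(n_samples, 0, noise_sd), 0.01), 0.99)
  names(auc) <- samples
  list(expression = expr, auc = auc, informative = informative, weights = w)
}

#' Simulate a toy single-cell UMI count matrix (negative binomial)
#'
#' Minimal cells x genes generator for QC-filter tests: NB counts with
#' per-cell size factors, a designated block of mitochondrial genes, and
#' optional planted QC violations.
#'
#' @param n_cells,n_genes dimensions.
#' @param n_mito number of mitochondrial genes (flagged `MT-` prefix).
#' @param mu,size negative-binomial mean and dispersion per gene-cell.
#' @param seed integer seed.
#' @return list `counts` (cells x genes integer matrix), `mito` (logical
#'   per gene).
#' @export
simulate_cell_counts <- function(n_cells = 200L, n_genes = 500L,
                                 n_mito = 13L, mu = 0.8, size = 2, seed = 1L) {
  set.seed(as.integer(seed))
  genes <- c(sprintf("MT-G%02d", seq_len(n_mito)),
             sprintf("G%04d", seq_len(n_genes - n_mito)))
  sf <- stats::rlnorm(n_cells, 0, 0.3)
  counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu * rep(sf, times = n_genes),
                                  size = size),
                   nrow = n_cells,
                   dimnames = list(sprintf("cell%04d", seq_len(n_cells)), genes))
  list(counts = counts, mito = startsWith(genes, "MT-"))
}

#' Simulate clustered single-cell counts with planted marker genes
#'
#' Two (or more) clusters of NB counts; the first `n_markers` genes are
#' upregulated `fold`-fold in cluster 1. Used for marker-recovery tests of
#' [cluster_signature].
#'
#' @param cells_per_cluster cells in each cluster.
#' @param n_clusters number of clusters.
#' @param n_genes genes.
#' @param n_markers planted cluster-1 markers.
#' @param fold marker fold-change.
#' @param mu,size NB baseline mean and dispersion.
#' @param seed integer seed.
#' @return list `counts` (cells x genes), `labels` (cluster per cell),
#'   `markers` (gene names).
#' @export
simulate_cluster_counts <- function(cells_per_cluster = 50L, n_clusters = 2L,
                                    n_genes = 300L, n_markers = 30L,
                                    fold = 4, mu = 2, size = 2, seed = 1L) {
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))
  n_cells <- cells_per_cluster * n_clusters
  labels <- rep(sprintf("C%d", seq_len(n_clusters)), each = cells_per_cluster)
  mu_mat <- matrix(mu, nrow = n_cells, ncol = n_genes)
  mu_mat[labels == "C1", seq_len(n_markers)] <- mu * fold
  counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = as.vector(mu_mat),
                                  size = size),
                   nrow = n_cells,
                   dimnames = list(sprintf("cell%04d", seq_len(n_cells)), genes))
  list(counts = counts, labels = stats::setNames(labels, rownames(counts)),
       markers = genes[seq_len(n_markers)])
}

#' Simulate exponential survival data with a planted hazard ratio
#'
#' Event times are exponential with rate `lambda0 * exp(beta * x)`;
#' censoring is independent exponential.
#'
#' @param n subjects.
#' @param beta log hazard ratio per unit covariate.
#' @param covariate `"binary"` (x in \{0, 1\}, balanced) or `"normal"`
#'   (standard normal score).
#' @param lambda0 baseline hazard (events per month).
#' @param censor_rate censoring hazard; 0 disables censoring (every
#'   subject's event is observed).
#' @param seed integer seed.
#' @return data.frame `patient_id`, `time_months`, `event`, `score`.
#' @export
simulate_survival <- function(n = 500L, beta = log(2),
                              covariate = c("binary", "normal"),
                              lambda0 = 0.02, censor_rate = 0.005,
                              seed = 1L) {
  covariate <- match.arg(covariate)
  set.seed(as.integer(seed))
  x <- if (covariate == "binary") rep(0:1, length.out = n) else stats::rnorm(n)
  ev <- stats::rexp(n, lambda0 * exp(beta * x))
  cn <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  data.frame(patient_id = sprintf("S%04d", seq_len(n)),
             time_months = pmin(ev, cn), event = as.integer(ev <= cn),
             score = x, stringsAsFactors = FALSE)
}

#' Simulate a Hill-model dose-response combination grid
#'
#' Single agents follow the median-effect (Hill) model
#' `fa = 1 / (1 + (Dm / D)^m)`. Combination wells are Loewe-additive —
#' the effect level at which the dose pair satisfies
#' `d1/Dx1(fa) + d2/Dx2(fa) = 1` — plus an additive inhibition `offset`
#' (positive offset = planted synergy), optionally with Gaussian noise.
#'
#' @param doses_a,doses_b positive dose vectors (the zero margins are added
#'   automatically).
#' @param m_a,Dm_a,m_b,Dm_b Hill slope and median-effect dose per drug.
#' @param offset additive inhibition excess on combination wells.
#' @param noise_sd Gaussian noise SD on all wells.
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return an `lp_dose_grid` (see [dose_response_grid]).
#' @export
simulate_dose_grid <- function(doses_a, doses_b, m_a = 2, Dm_a = 10,
                               m_b = 2, Dm_b = 10, offset = 0,
                               noise_sd = 0, seed = 1L) {
  stopifnot(all(doses_a > 0), all(doses_b > 0))
  if (noise_sd > 0) set.seed(as.integer(seed))
  hill <- function(D, m, Dm) ifelse(D <= 0, 0, 1 / (1 + (Dm / D)^m))
  da <- c(0, sort(doses_a)); db <- c(0, sort(doses_b))
  inh <- matrix(0, nrow = length(da), ncol = length(db),
                dimnames = list(format(da, trim = TRUE),
                                format(db, trim = TRUE)))
  for (i in seq_along(da)) {
    for (j in seq_along(db)) {
      d1 <- da[i]; d2 <- db[j]
      base <- if (d1 == 0 && d2 == 0) {
        0
      } else if (d2 == 0) {
        hill(d1, m_a, Dm_a)
      } else if (d1 == 0) {
        hill(d2, m_b, Dm_b)
      } else {
        loewe_fa(d1, d2, m_a, Dm_a, m_b, Dm_b) + offset
      }
      if (noise_sd > 0) base <- base + stats::rnorm(1, 0, noise_sd)
      inh[i, j] <- min(max(base, 0), 0.999)
    }
  }
  dose_response_grid(da, db, inh)
}

# Effect level fa at which (d1, d2) is exactly Loewe-additive:
# d1 / Dx1(fa) + d2 / Dx2(fa) = 1 with Dx = Dm * (fa/(1-fa))^(1/m).
loewe_fa <- function(d1, d2, m_a, Dm_a, m_b, Dm_b) {
  g <- function(fa) {
    d1 / (Dm_a * (fa / (1 - fa))^(1 / m_a)) +
      d2 / (Dm_b * (fa / (1 - fa))^(1 / m_b)) - 1
  }
  stats::uniroot(g, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}
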