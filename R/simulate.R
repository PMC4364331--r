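#' Configuration for the synthetic cohort generators
#'
#' Collects and validates every parameter of the latent cell-type mixture
#' model behind [generate_phenotype_cohort()] and
#' [generate_development_cohort()]. Each cell type drives one "program" of
#' signature genes; the growth phenotype is coupled to the proliferating cell
#' fraction (not to any single gene), and all noise is additive Gaussian on
#' the log2 scale.
#'
#' @param n_genes total genes on the array.
#' @param n_celltypes number of latent cell types / expression programs.
#' @param signatures_per_celltype signature genes planted per cell type;
#'   `n_celltypes * signatures_per_celltype` must not exceed `n_genes`.
#' @param phenotype_effect target Pearson correlation, in \[0, 0.999\], between
#'   each growth-program gene and ADG/kg liveweight.
#' @param noise_sd Gaussian noise SD in log2 units.
#' @param signature_amplitude log2 amplitude of the program signal per unit of
#'   (standardized) latent driver.
#' @param dirichlet_concentration positive Dirichlet concentration per cell
#'   type for the phenotype-cohort fractions; defaults to a muscle-fiber
#'   dominated composition.
#' @param stages data.frame with `stage` labels and strictly increasing
#'   `age_days` (negative = days before birth); default is the ten-stage
#'   60/135/195 dpc, birth, 3/7/12/20/25/30-month course.
#' @param genotype_offsets named list: cell type -> named numeric vector of
#'   log2 shifts applied to the high-marbling genotype at given stages. The
#'   default raises the ECM program by +1 log2 at 12 and 25 months.
#' @param n_animals_per_group animals per stage per genotype in the
#'   development cohort (3 or 4; default 4).
#' @param n_animals total animals in the phenotype cohort (default 48, in a
#'   2 site x 2 treatment layout).
#' @param treatment_effect shift (in driver SD units) added to the
#'   proliferating-cell driver of HGP-treated animals; default 0.
#' @param seed integer seed; all randomness flows from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_celltypes = 6,
                              signatures_per_celltype = 50,
                              phenotype_effect = 0.7,
                              noise_sd = 0.5,
                              signature_amplitude = 1,
                              dirichlet_concentration = NULL,
                              stages = default_stages(),
                              genotype_offsets = list(
                                fibroblast_ecm = c("12mo" = 1, "25mo" = 1)),
                              n_animals_per_group = 4,
                              n_animals = 48,
                              treatment_effect = 0,
                              seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(n_celltypes, "n_celltypes")
  assert_count(signatures_per_celltype, "signatures_per_celltype", min = 0L)
  assert_count(n_animals_per_group, "n_animals_per_group", min = 2L)
  assert_count(n_animals, "n_animals", min = 4L)
  if (signatures_per_celltype * n_celltypes > n_genes) {
    stopf("signatures_per_celltype x n_celltypes exceeds n_genes")
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (signature_amplitude <= 0) stopf("signature_amplitude must be positive")
  if (phenotype_effect < 0 || phenotype_effect > 0.999) {
    stopf("phenotype_effect must lie in [0, 0.999]")
  }
  if (!all(c("stage", "age_days") %in% names(stages))) {
    stopf("stages needs columns stage and age_days")
  }
  if (any(diff(stages$age_days) <= 0)) stopf("stage ages must be strictly increasing")
  celltypes <- celltype_names(n_celltypes)
  if (is.null(dirichlet_concentration)) {
    base <- c(2, 2, 2, 1, 1, 12)  # fiber-dominated mixture
    dirichlet_concentration <- if (n_celltypes <= 6) {
      base[seq_len(n_celltypes)]
    } else {
      c(base, rep(1, n_celltypes - 6))
    }
  }
  if (length(dirichlet_concentration) != n_celltypes ||
      any(dirichlet_concentration <= 0)) {
    stopf("dirichlet_concentration needs %d positive values", n_celltypes)
  }
  bad <- setdiff(names(genotype_offsets), celltypes)
  if (length(bad)) stopf("genotype_offsets refer to unknown cell type(s): %s",
                         paste(bad, collapse = ", "))
  for (ct in names(genotype_offsets)) {
    bad_stage <- setdiff(names(genotype_offsets[[ct]]), stages$stage)
    if (length(bad_stage)) stopf("genotype_offsets for %s refer to unknown stage(s): %s",
                                 ct, paste(bad_stage, collapse = ", "))
  }
  structure(list(
    n_genes = as.integer(n_genes), n_celltypes = as.integer(n_celltypes),
    signatures_per_celltype = as.integer(signatures_per_celltype),
    phenotype_effect = phenotype_effect, noise_sd = noise_sd,
    signature_amplitude = signature_amplitude,
    dirichlet_concentration = dirichlet_concentration,
    stages = stages, genotype_offsets = genotype_offsets,
    n_animals_per_group = as.integer(n_animals_per_group),
    n_animals = as.integer(n_animals),
    treatment_effect = treatment_effect,
    celltypes = celltypes, seed = as.integer(seed)), class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_stages <- function() {
  data.frame(
    stage = c("60dpc", "135dpc", "195dpc", "birth", "3mo", "7mo",
              "12mo", "20mo", "25mo", "30mo"),
    age_days = c(-220, -145, -85, 0, 90, 210, 365, 608, 760, 912),
    stringsAsFactors = FALSE)
}

celltype_names <- function(n) {
  canonical <- c("fibroblast_ecm", "fap_cellcycle", "endothelial_angio",
                 "satellite", "adipocyte", "myofiber")
  if (n <= length(canonical)) canonical[seq_len(n)]
  else c(canonical, sprintf("program%02d", seq_len(n - length(canonical))))
}

# Cell type of each gene: signature blocks first, then background.
assign_genes <- function(config) {
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  ct <- rep("background", config$n_genes)
  idx <- 0L
  for (t in config$celltypes) {
    if (config$signatures_per_celltype == 0) break
    ct[idx + seq_len(config$signatures_per_celltype)] <- t
    idx <- idx + config$signatures_per_celltype
  }
  stats::setNames(ct, genes)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Standardize to mean 0, sd 1; constant vectors map to all-zero.
zvec <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a synthetic growth-phenotype cohort
#'
#' Emulates a single-timepoint steer cohort (default 48 animals in a 2 site x
#' 2 HGP-treatment layout): per-animal cell-type fractions are drawn from a
#' Dirichlet, each cell type's signature genes track the standardized fraction
#' of that cell type with amplitude `signature_amplitude` plus Gaussian log2
#' noise, and the ADG/kg liveweight phenotype is an affine function of the
#' proliferating ("fap_cellcycle", or the last cell type if fewer than two)
#' fraction with noise calibrated analytically so each growth-program gene
#' attains `phenotype_effect` correlation with the phenotype in expectation.
#' If `noise_sd` makes the target unreachable even with a noiseless phenotype,
#' the phenotype is generated noiseless and a warning reports the achievable
#' correlation.
#'
#' @param config a [simulation_config()].
#' @return A list with `expression` (genes x samples log2 matrix), `samples`
#'   (sample table with site, treatment, adg_per_kg, imf_pct) and `truth`
#'   (celltype_of_gene, true_fractions, true_phenotype_corr, growth_celltype,
#'   seed).
#' @export
generate_phenotype_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_animals
    sample_ids <- sprintf("B%02d", seq_len(n))
    site <- rep(c("NSW", "WA"), each = ceiling(n / 2))[seq_len(n)]
    treatment <- character(n)
    for (s in unique(site)) {
      ix <- which(site == s)
      treatment[ix] <- rep(c("HGP", "control"), each = ceiling(length(ix) / 2))[
        seq_along(ix)]
    }
    fractions <- rdirichlet(n, config$dirichlet_concentration)
    colnames(fractions) <- config$celltypes
    rownames(fractions) <- sample_ids
    growth_ct <- if (config$n_celltypes >= 2) "fap_cellcycle" else config$celltypes[1]
    drivers <- apply(fractions, 2L, zvec)
    drivers[, growth_ct] <- drivers[, growth_ct] +
      config$treatment_effect * (treatment == "HGP")
    ct_of_gene <- assign_genes(config)
    genes <- names(ct_of_gene)
    baseline <- stats::runif(config$n_genes, 4, 12)
    A <- config$signature_amplitude
    expr <- matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                   nrow = config$n_genes, dimnames = list(genes, sample_ids))
    expr <- expr + baseline
    for (t in config$celltypes) {
      sel <- ct_of_gene == t
      if (any(sel)) {
        expr[sel, ] <- expr[sel, ] + rep(A * drivers[, t], each = sum(sel))
      }
    }
    # Phenotype noise solving corr(gene, phenotype) = phenotype_effect given
    # corr(gene, driver) = A / sqrt(A^2 + noise_sd^2).
    r_gene <- A / sqrt(A^2 + config$noise_sd^2)
    r <- config$phenotype_effect
    if (r > r_gene) {
      warnf(paste("phenotype_effect %.3f unreachable at noise_sd %.3f;",
                  "generating a noiseless phenotype (achievable r = %.3f)"),
            r, config$noise_sd, r_gene)
      tau <- 0
    } else if (r == 0) {
      tau <- Inf
    } else {
      tau <- sqrt(A^2 / (r^2 * (A^2 + config$noise_sd^2)) - 1)
    }
    pheno_z <- if (is.infinite(tau)) {
      stats::rnorm(n)
    } else {
      drivers[, growth_ct] + stats::rnorm(n, sd = tau)
    }
    adg_per_kg <- 0.0022 + 0.0004 * pheno_z
    imf_ct <- if ("adipocyte" %in% config$celltypes) "adipocyte" else config$celltypes[1]
    imf_pct <- 5.5 + 1.2 * drivers[, imf_ct] + stats::rnorm(n, sd = 0.5)
    samples <- data.frame(
      sample_id = sample_ids, cohort = "phenotype", genotype = "brahman",
      stage = "slaughter", age_days = 608, treatment = treatment, site = site,
      adg_per_kg = adg_per_kg, imf_pct = imf_pct, stringsAsFactors = FALSE)
    true_corr <- ifelse(ct_of_gene == growth_ct, r, NA_real_)
    names(true_corr) <- genes
    list(expression = expr, samples = samples,
         truth = list(celltype_of_gene = ct_of_gene, true_fractions = fractions,
                      true_phenotype_corr = true_corr,
                      growth_celltype = growth_ct, seed = config$seed))
  })
}

# Canonical + seeded-random stage profiles, one row per cell type, each
# standardized to mean 0 / sd 1 across stages. Must be called inside the
# cohort's seeded stream.
celltype_profiles <- function(config) {
  n_stage <- nrow(config$stages)
  prof <- matrix(0, nrow = config$n_celltypes, ncol = n_stage,
                 dimnames = list(config$celltypes, config$stages$stage))
  shapes <- list(
    # ECM program: rises to birth, declines steadily after birth
    fibroblast_ecm = c(0.8, 1.0, 1.2, 1.4, 0.9, 0.4, -0.2, -0.8, -1.2, -1.5),
    # proliferation: high prenatally, postnatal dip, late resurgence
    fap_cellcycle = c(1.5, 1.3, 1.0, 0.6, 0.0, -0.6, -1.0, -0.3, 0.1, -0.6))
  for (t in config$celltypes) {
    if (!is.null(shapes[[t]]) && n_stage == 10) {
      prof[t, ] <- zvec(shapes[[t]])
    } else {
      raw <- stats::rnorm(n_stage)
      sm <- stats::filter(raw, rep(1 / 3, 3), sides = 2)
      sm[is.na(sm)] <- raw[is.na(sm)]
      prof[t, ] <- zvec(as.numeric(sm))
    }
  }
  prof
}

#' Generate a synthetic developmental time-course cohort
#'
#' Emulates the two-genotype development series (high-muscling vs
#' high-marbling crosses) sampled at ten ordered stages from 60 days post
#' conception to 30 months, with 3-4 animals per stage per genotype. Each cell
#' type follows a smooth stage profile (the ECM program declines after birth;
#' the proliferation program dips then resurges; remaining programs get
#' seeded smooth random profiles), genotype offsets are added to the
#' high-marbling animals at the configured stages, and signature genes track
#' their program's profile plus Gaussian log2 noise.
#'
#' @param config a [simulation_config()].
#' @return A list with `expression`, `samples` (stage, age_days, genotype) and
#'   `truth` (celltype_of_gene, true_fractions as softmax compositions of the
#'   latent program activities, stage profiles, applied offsets, seed).
#' @export
generate_development_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_animals_per_group < 3 || config$n_animals_per_group > 4) {
    stopf("n_animals_per_group must be 3 or 4 for the development cohort")
  }
  with_seed(config$seed + 1L, {
    genotypes <- c("highmarble", "highmuscle")
    stages <- config$stages
    layout <- expand.grid(animal = seq_len(config$n_animals_per_group),
                          genotype = genotypes, stage = stages$stage,
                          stringsAsFactors = FALSE)
    layout$stage <- as.character(layout$stage)
    sample_ids <- sprintf("dev_%s_%s_%d",
                          ifelse(layout$genotype == "highmarble", "wxh", "pxh"),
                          layout$stage, layout$animal)
    prof <- celltype_profiles(config)
    offsets <- matrix(0, nrow = config$n_celltypes, ncol = nrow(layout),
                      dimnames = list(config$celltypes, sample_ids))
    for (ct in names(config$genotype_offsets)) {
      sh <- config$genotype_offsets[[ct]]
      for (s in names(sh)) {
        sel <- layout$stage == s & layout$genotype == "highmarble"
        offsets[ct, sel] <- offsets[ct, sel] + sh[[s]]
      }
    }
    activity <- prof[, match(layout$stage, stages$stage), drop = FALSE] + offsets
    ct_of_gene <- assign_genes(config)
    genes <- names(ct_of_gene)
    baseline <- stats::runif(config$n_genes, 4, 12)
    expr <- matrix(stats::rnorm(config$n_genes * nrow(layout), sd = config$noise_sd),
                   nrow = config$n_genes, dimnames = list(genes, sample_ids))
    expr <- expr + baseline
    A <- config$signature_amplitude
    for (t in config$celltypes) {
      sel <- ct_of_gene == t
      if (any(sel)) {
        expr[sel, ] <- expr[sel, ] + rep(A * activity[t, ], each = sum(sel))
      }
    }
    fractions <- t(apply(activity, 2L, function(a) {
      e <- exp(a - max(a))
      e / sum(e)
    }))
    colnames(fractions) <- config$celltypes
    samples <- data.frame(
      sample_id = sample_ids, cohort = "development", genotype = layout$genotype,
      stage = layout$stage,
      age_days = stages$age_days[match(layout$stage, stages$stage)],
      treatment = "none", site = "timecourse",
      adg_per_kg = NA_real_, imf_pct = NA_real_, stringsAsFactors = FALSE)
    list(expression = expr, samples = samples,
         truth = list(celltype_of_gene = ct_of_gene, true_fractions = fractions,
                      true_phenotype_corr = stats::setNames(
                        rep(NA_real_, length(genes)), genes),
                      stage_profiles = prof,
                      genotype_offsets = config$genotype_offsets,
                      seed = config$seed))
  })
}

#' Generate a GO-like annotation matched to a synthetic truth
#'
#' Builds one term per planted program containing exactly its signature genes,
#' plus random background terms so enrichment has a realistic null. Background
#' terms are drawn (by default) from the background genes only, so they carry
#' no planted signal.
#'
#' @param truth the `truth` element of a generated cohort.
#' @param n_background_terms number of random background terms.
#' @param term_size_range inclusive size range for background terms.
#' @param exclude_planted draw background terms only from background genes
#'   (default TRUE).
#' @param seed RNG seed (default: derived from the truth seed).
#' @return A `gene_annotation` (named list of member vectors) serializable with
#'   [write_gmt()]. Planted terms are named `PROG_<celltype>`.
#' @export
generate_annotation <- function(truth, n_background_terms = 40,
                                term_size_range = c(5, 50),
                                exclude_planted = TRUE,
                                seed = truth$seed + 77L) {
  assert_count(n_background_terms, "n_background_terms", min = 0L)
  genes <- names(truth$celltype_of_gene)
  if (max(term_size_range) > length(genes)) {
    stopf("term_size_range exceeds the gene universe (%d)", length(genes))
  }
  planted_ct <- setdiff(unique(truth$celltype_of_gene), "background")
  terms <- lapply(planted_ct, function(t) {
    genes[truth$celltype_of_gene == t]
  })
  names(terms) <- paste0("PROG_", planted_ct)
  pool <- if (exclude_planted) genes[truth$celltype_of_gene == "background"] else genes
  with_seed(seed, {
    if (n_background_terms > 0) {
      bg <- lapply(seq_len(n_background_terms), function(i) {
        size <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
        sample(pool, min(size, length(pool)))
      })
      names(bg) <- sprintf("BG%03d", seq_len(n_background_terms))
      terms <- c(terms, bg)
    }
    structure(terms,
              descriptions = stats::setNames(names(terms), names(terms)),
              class = "gene_annotation")
  })
}
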