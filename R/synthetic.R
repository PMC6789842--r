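# Synthetic cohorts with the statistical structure the pipeline assumes:
# three diagnosis groups of equal size, planted co-expression modules whose
# latent factors follow disease archetypes, covariate effects (age, sex,
# PMI), clinical traits coupled to module latents, and a peptide layer for
# the quantification stage.

archetype_patterns <- list(                       # (control, AsymAD, AD)
  stable                    = c(0, 0, 0),         # in latent sd units
  progressive_increase      = c(0, 0.9, 1.8),
  progressive_decrease      = c(0, -0.9, -1.8),
  early_decrease_then_stable = c(0, -1.4, -1.4),
  transient_up              = c(0, 1.4, -1.2),
  transient_down            = c(0, -1.4, 1.2)
)

#' Specification of a synthetic study design
#'
#' Defines the cohort and signal structure of a simulated label-free
#' proteomic study: 6 samples per diagnosis group by default, 8 planted
#' co-expression modules spanning the disease archetypes with sizes 25-120,
#' 300 unstructured noise proteins, linear covariate effects on a fraction
#' of proteins, and clinical traits coupled to module latent factors
#' (default: CERAD tracks the progressive-increase module and CASI the
#' large progressive-decrease module, both at r = 0.7).
#'
#' @param n_per_group samples per diagnosis group.
#' @param module_designs data.frame with columns `size`, `archetype` (one
#'   of stable, progressive_increase, progressive_decrease,
#'   early_decrease_then_stable, transient_up, transient_down) and
#'   `cor_target` (target median within-module correlation in (0, 1)).
#' @param n_noise_proteins unstructured proteins appended to the matrix.
#' @param covariate_effects list with `b_age` (log2 units / year), `b_sex`
#'   (log2 units), `b_pmi` (log2 units / hour) and `affected_fraction`.
#' @param trait_couplings list of `list(module = <index into
#'   module_designs>, trait = <"casi"|"cerad"|"braak">, r = <target>)`.
#' @param noise_sd residual sd of noise proteins, log2 units.
#' @param amplitude module signal amplitude, log2 units.
#' @param seed integer seed (mandatory); all randomness flows from it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = 6L,
                           module_designs = default_module_designs(),
                           n_noise_proteins = 300L,
                           covariate_effects = list(b_age = 0.05, b_sex = 0.4,
                                                    b_pmi = 0.1,
                                                    affected_fraction = 0.3),
                           trait_couplings = default_trait_couplings(),
                           noise_sd = 0.5, amplitude = 0.5, seed) {
  if (missing(seed)) stopf("seed is mandatory in a synthetic_spec")
  stopifnot(all(module_designs$size >= 2),
            all(module_designs$cor_target > 0 & module_designs$cor_target < 1),
            all(module_designs$archetype %in% names(archetype_patterns)))
  # couplings must reference planted modules; drop any that do not
  ok <- vapply(trait_couplings, function(cp)
    cp$module >= 1 && cp$module <= nrow(module_designs), logical(1))
  if (!all(ok)) {
    wp_log("dropping %d trait coupling(s) outside the module designs",
           sum(!ok))
    trait_couplings <- trait_couplings[ok]
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 module_designs = module_designs,
                 n_noise_proteins = as.integer(n_noise_proteins),
                 covariate_effects = covariate_effects,
                 trait_couplings = trait_couplings,
                 noise_sd = noise_sd, amplitude = amplitude,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_module_designs <- function() {
  data.frame(
    size = c(120L, 100L, 80L, 60L, 50L, 40L, 30L, 25L),
    archetype = c("progressive_decrease", "stable", "transient_up",
                  "progressive_increase", "early_decrease_then_stable",
                  "transient_down", "progressive_increase", "stable"),
    cor_target = 0.6,
    stringsAsFactors = FALSE)
}

#' @rdname synthetic_spec
#' @export
default_trait_couplings <- function() {
  list(list(module = 4L, trait = "cerad", r = 0.7),
       list(module = 1L, trait = "casi", r = 0.7))
}

#' Generate a synthetic clinical cohort
#'
#' Draws one sample trait table consistent with the study design: equal
#' group sizes, ages matched across groups (a shared age backbone plus
#' small per-sample jitter), PMI uniform in 2.5-8.5 h, and
#' pathology/cognition scores consistent with the diagnosis (controls: low
#' CERAD/Braak, high CASI; AsymAD: pathology with control-like CASI; AD:
#' pathology with reduced CASI).
#'
#' @param spec a [synthetic_spec].
#' @return trait data.frame with `sample_id`, `group`, `age`, `sex`,
#'   `pmi`, `casi`, `cerad`, `braak`.
#' @export
generate_cohort <- function(spec) {
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  npg <- spec$n_per_group
  groups <- rep(c("control", "AsymAD", "AD"), each = npg)
  n <- length(groups)
  base_age <- sort(stats::runif(npg, 76, 94))       # shared backbone: matched
  age <- rep(base_age, 3) + stats::rnorm(n, 0, 0.75)
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "F", "M")
  pmi <- stats::runif(n, 2.5, 8.5)
  casi <- c(stats::rnorm(npg, 92, 2), stats::rnorm(npg, 91, 2),
            stats::rnorm(npg, 72, 6))
  cerad <- c(stats::runif(npg, 0, 0.5), stats::runif(npg, 2, 3),
             stats::runif(npg, 2, 3))
  braak <- c(stats::runif(npg, 0, 2), stats::runif(npg, 3, 5),
             stats::runif(npg, 4, 6))
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             group = factor(groups, levels = c("control", "AsymAD", "AD")),
             age = age, sex = sex, pmi = pmi, casi = casi,
             cerad = cerad, braak = braak, stringsAsFactors = FALSE)
}

#' Generate a protein abundance matrix with planted modules
#'
#' Per module, a latent factor is built as the archetype's group-mean
#' pattern plus per-sample noise (then standardized); member proteins are
#' `loading * latent + independent noise`, the noise calibrated so the
#' median within-module correlation hits the design target. Covariate
#' effects are added linearly (random sign per protein and covariate) to a
#' random fraction of proteins. Traits named in `trait_couplings` are
#' regenerated as a blend of the module latent and noise achieving the
#' target correlation, then mapped affinely to the trait's natural scale
#' (kept continuous, uncapped). Noise proteins are independent Gaussians.
#'
#' @param spec a [synthetic_spec].
#' @param traits cohort from [generate_cohort]; generated when `NULL`.
#' @return list with `matrix` ([protein_matrix], log2 scale),
#'   `true_partition` (named vector, `"M1"`... by design order and
#'   `"unassigned"` for noise proteins), `latents` (modules x samples),
#'   `traits` (possibly updated by couplings), `covariate_effects`
#'   (proteins x covariates matrix of planted slopes).
#' @export
generate_abundance <- function(spec, traits = NULL) {
  if (is.null(traits)) traits <- generate_cohort(spec)
  with_seed(spec$seed + 1L, generate_abundance_impl(spec, traits))
}

generate_abundance_impl <- function(spec, traits) {
  md <- spec$module_designs
  n_samp <- nrow(traits)
  grp_idx <- as.integer(traits$group)               # 1 control, 2 AsymAD, 3 AD
  n_mod_prot <- sum(md$size)
  n_prot <- n_mod_prot + spec$n_noise_proteins
  ids <- sprintf("P%04d", seq_len(n_prot))
  genes <- sprintf("GENE%04d", seq_len(n_prot))
  amp <- spec$amplitude

  latents <- matrix(NA_real_, nrow(md), n_samp,
                    dimnames = list(paste0("M", seq_len(nrow(md))),
                                    traits$sample_id))
  vals <- matrix(NA_real_, n_prot, n_samp, dimnames = list(ids, traits$sample_id))
  truth <- stats::setNames(rep("unassigned", n_prot), ids)
  row <- 1L
  for (m in seq_len(nrow(md))) {
    pat <- archetype_patterns[[md$archetype[m]]]
    f <- pat[grp_idx] + stats::rnorm(n_samp, 0, 0.6)
    f <- as.numeric(scale(f))                       # unit variance latent
    latents[m, ] <- f
    size <- md$size[m]
    s_noise <- amp * sqrt(1 / md$cor_target[m] - 1)
    loading <- stats::runif(size, 0.9, 1.1) * amp
    mu <- stats::runif(size, 20, 30)
    block <- mu + tcrossprod(loading, f) +
      matrix(stats::rnorm(size * n_samp, 0, s_noise), size, n_samp)
    idx <- row:(row + size - 1L)
    vals[idx, ] <- block
    truth[idx] <- paste0("M", m)
    row <- row + size
  }
  if (spec$n_noise_proteins > 0) {
    idx <- row:(row + spec$n_noise_proteins - 1L)
    vals[idx, ] <- stats::runif(length(idx), 20, 30) +
      matrix(stats::rnorm(length(idx) * n_samp, 0, spec$noise_sd),
             length(idx), n_samp)
  }

  # planted covariate effects on a random subset of proteins
  ce <- spec$covariate_effects
  slopes <- matrix(0, n_prot, 3, dimnames = list(ids, c("age", "sex", "pmi")))
  n_aff <- round((ce$affected_fraction %||% 0) * n_prot)
  if (n_aff > 0) {
    aff <- sample.int(n_prot, n_aff)
    sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
    slopes[aff, "age"] <- sgn(n_aff) * ce$b_age
    slopes[aff, "sex"] <- sgn(n_aff) * ce$b_sex
    slopes[aff, "pmi"] <- sgn(n_aff) * ce$b_pmi
    covs <- cbind(age = traits$age - mean(traits$age),
                  sex = as.numeric(traits$sex == "F") -
                    mean(traits$sex == "F"),
                  pmi = traits$pmi - mean(traits$pmi))
    vals <- vals + slopes %*% t(covs)
  }

  # couple selected traits to module latents at a target correlation
  for (cp in spec$trait_couplings) {
    f <- latents[cp$module, ]
    z <- cp$r * f + sqrt(1 - cp$r^2) * stats::rnorm(n_samp)
    z <- as.numeric(scale(z))
    traits[[cp$trait]] <- switch(cp$trait,
      cerad = 1.5 + 0.9 * z,
      braak = 3 + 1.8 * z,
      casi  = 85 + 9 * z,
      stop("unsupported coupled trait: ", cp$trait))
  }

  pm <- protein_matrix(vals, protein_ids = ids, gene_symbols = genes,
                       sample_ids = traits$sample_id, is_log2 = TRUE)
  list(matrix = pm, true_partition = truth, latents = latents,
       traits = traits, covariate_effects = slopes)
}

#' Generate a peptide-level table from a protein matrix
#'
#' Emulates label-free acquisition downstream of a known protein abundance
#' matrix: each protein yields 1-8 tryptic peptides with multiplicative
#' lognormal ionization efficiencies; per-sample peptide intensities are
#' `efficiency * linear abundance * lognormal noise`; spectral counts grow
#' monotonically (Poisson) with log intensity; a configurable fraction of
#' peptides is non-unique. Each protein is assigned a membrane:soluble
#' spectral-count ratio drawn from `class_ratios`, and counts are split
#' binomially between the two fraction labels.
#'
#' @param pm a [protein_matrix]; values must be on the linear (non-log)
#'   scale (use `2^x` for log2 data).
#' @param spec a [synthetic_spec] (supplies the seed).
#' @param peptide_noise_sd sd of the lognormal intensity noise (log2 units).
#' @param unique_fraction probability a peptide is unique to its group.
#' @param class_ratios named numeric vector of membrane:soluble count
#'   ratios; each protein samples one class.
#' @return list with `peptides` (data.frame in the standard peptide-table
#'   layout) and `protein_class` (named character vector).
#' @export
generate_peptides <- function(pm, spec, peptide_noise_sd = 0.15,
                              unique_fraction = 0.9,
                              class_ratios = c(membrane_bound = 4,
                                               neutral = 1,
                                               soluble_like = 0.25)) {
  if (pm$is_log2) stopf("generate_peptides expects a linear-scale matrix")
  with_seed(spec$seed + 2L,
            generate_peptides_impl(pm, peptide_noise_sd, unique_fraction,
                                   class_ratios))
}

generate_peptides_impl <- function(pm, peptide_noise_sd, unique_fraction,
                                   class_ratios) {
  v <- pm$values
  prot_ids <- rownames(v)
  n_samp <- ncol(v)
  cls <- sample(names(class_ratios), length(prot_ids), replace = TRUE)
  names(cls) <- prot_ids
  out <- vector("list", length(prot_ids))
  for (i in seq_along(prot_ids)) {
    pid <- prot_ids[i]
    npep <- sample(1:8, 1)
    eff <- stats::rlnorm(npep, meanlog = 0, sdlog = 1)
    pep_ids <- sprintf("%s_pep%02d", pid, seq_len(npep))
    uniq <- stats::runif(npep) < unique_fraction
    ratio <- class_ratios[[cls[pid]]]
    p_mem <- ratio / (1 + ratio)
    ab <- v[i, ]
    inten <- outer(eff, ab) *
      2^matrix(stats::rnorm(npep * n_samp, 0, peptide_noise_sd), npep, n_samp)
    counts <- matrix(stats::rpois(npep * n_samp,
                                  lambda = pmax(log2(1 + inten) / 4, 0.2)),
                     npep, n_samp)
    mem_counts <- matrix(stats::rbinom(npep * n_samp, as.vector(counts), p_mem),
                         npep, n_samp)
    sol_counts <- counts - mem_counts
    long <- data.frame(
      peptide_sequence = rep(pep_ids, times = 2 * n_samp),
      protein_group = pid,
      gene_symbol = unname(pm$gene_symbols[pid]),
      sample_id = rep(rep(colnames(v), each = npep), times = 2),
      fraction = rep(c("membrane", "soluble"), each = npep * n_samp),
      intensity = c(as.vector(inten) * p_mem, as.vector(inten) * (1 - p_mem)),
      spectral_counts = c(as.vector(mem_counts), as.vector(sol_counts)),
      is_unique = rep(uniq, times = 2 * n_samp),
      stringsAsFactors = FALSE)
    out[[i]] <- long
  }
  peptides <- do.call(rbind, out)
  rownames(peptides) <- NULL
  list(peptides = peptides, protein_class = cls)
}
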