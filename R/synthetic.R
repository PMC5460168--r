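# Synthetic paired two-species expression meta-sets with planted module
# structure.  The generator is the ground-truth source for every downstream
# stage: module detection, consensus construction, preservation statistics,
# trait association and classification are all validated against the design
# it encodes.

#' Describe a synthetic two-species meta-set design
#'
#' A design specifies, per species, the gene universe, the ortholog subset
#' shared between species, a set of planted co-expression modules, the study
#' layout (samples per study, with per-study batch offsets), and trait links
#' that couple binary sample groups to module activity.
#'
#' Planted modules follow a single-factor model: gene g in module m is
#' `x_g = r_g * f_m + noise_sd * sqrt(1 - r_g^2) * e`, so at `noise_sd = 1`
#' the pairwise correlation of genes g, h is `r_g * r_h`.  The per-gene
#' factor correlations `r_g = sqrt(within_cor) * v_g` are spread over the
#' widest interval (mean-1 `v_g`) compatible with the mean pairwise
#' correlation equalling `within_cor`, planting a hub gradient: high-`r_g`
#' genes are the module's hubs, mirroring the intramodular-connectivity
#' heterogeneity of real co-expression modules.  Modules flagged `shared`
#' are placed inside the ortholog
#' subset and use identical loadings on ortholog-matched genes in both
#' species; unshared modules are placed outside the ortholog subset so the
#' consensus network has clean negatives.
#'
#' Each trait link turns a random half of the samples (per species) into
#' trait members whose module factor is shifted by `effect`; additionally one
#' designated marker gene of the linked module receives the same shift
#' directly, planting an unambiguous strongest gene for signature ranking.
#'
#' @param n_genes genes per species.
#' @param n_shared_orthologs size of the one-to-one ortholog subset.
#' @param modules data.frame with columns `label`, `size`, `shared`
#'   (logical), `within_cor` (in \[0, 1\]).
#' @param samples_per_study integer vector; one study per element, applied to
#'   both species.
#' @param batch_shift_sd sd of additive per-study, per-gene offsets.
#' @param noise_sd residual noise scale (1 = calibrated correlation).
#' @param trait_links data.frame with columns `trait`, `module`, `effect`.
#' @param seed integer seed; the whole meta-set is reproducible from it.
#' @return a `synthetic_design` list, validated.
#' @export
synthetic_design <- function(n_genes = 700,
                             n_shared_orthologs = 400,
                             modules = data.frame(
                               label = c("M1", "M2", "S1"),
                               size = c(80, 80, 80),
                               shared = c(TRUE, TRUE, FALSE),
                               within_cor = c(0.8, 0.8, 0.8)),
                             samples_per_study = c(30, 30),
                             batch_shift_sd = 0.5,
                             noise_sd = 1,
                             trait_links = data.frame(
                               trait = "disease",
                               module = "M1",
                               effect = 1.5),
                             seed = 1) {
  stopifnot(is.data.frame(modules),
            all(c("label", "size", "shared", "within_cor") %in% names(modules)))
  d <- list(n_genes = as.integer(n_genes),
            n_shared_orthologs = as.integer(n_shared_orthologs),
            modules = modules,
            samples_per_study = as.integer(samples_per_study),
            batch_shift_sd = batch_shift_sd,
            noise_sd = noise_sd,
            trait_links = trait_links,
            seed = as.integer(seed))
  class(d) <- "synthetic_design"
  validate_design(d)
  d
}

validate_design <- function(d) {
  m <- d$modules
  num <- c(d$n_genes, d$n_shared_orthologs, m$size, m$within_cor,
           d$samples_per_study, d$batch_shift_sd, d$noise_sd)
  if (any(!is.finite(num)))
    stop("design contains non-finite parameters")
  if (any(m$within_cor < 0 | m$within_cor > 1))
    stop("within_cor must lie in [0, 1]")
  if (d$noise_sd <= 0) stop("noise_sd must be positive")
  if (d$batch_shift_sd < 0) stop("batch_shift_sd must be nonnegative")
  if (sum(m$size) > d$n_genes)
    stop("module sizes exceed the gene budget (",
         sum(m$size), " > ", d$n_genes, ")")
  if (sum(m$size[m$shared]) > d$n_shared_orthologs)
    stop("shared module sizes exceed the ortholog subset")
  if (sum(m$size[!m$shared]) > d$n_genes - d$n_shared_orthologs)
    stop("species-specific module sizes exceed the non-ortholog gene budget")
  if (anyDuplicated(m$label)) stop("duplicated module labels")
  if (nrow(d$trait_links) > 0 &&
      !all(d$trait_links$module %in% m$label))
    stop("trait_links reference unknown modules")
  invisible(d)
}

#' Generate a paired two-species meta-set with planted modules
#'
#' Draws the expression matrices of both species under the factor model of
#' [synthetic_design()], together with the ground truth needed by downstream
#' tests: true module labels per species, the ortholog table, per-species
#' binary trait tables, two-class labels for the species-A classification
#' cohort, per-gene factor loadings and the planted marker gene of each
#' trait-linked module.
#'
#' @param design a `synthetic_design`.
#' @return list with elements `expr` (list `a`, `b` of genes x samples
#'   matrices), `study` (list of per-sample study labels) and `truth` (list:
#'   `modules` per species, `ortholog_table`, `trait_table` per species,
#'   `class_labels`, `loadings` per species, `markers`).
#' @export
simulate_meta_set <- function(design) {
  validate_design(design)
  set.seed(design$seed)
  n_samp <- sum(design$samples_per_study)
  study_of <- rep(seq_along(design$samples_per_study),
                  design$samples_per_study)

  gene_ids <- list(a = sprintf("gA%05d", seq_len(design$n_genes)),
                   b = sprintf("gB%05d", seq_len(design$n_genes)))
  ns <- design$n_shared_orthologs
  ortholog_table <- data.frame(species_a = gene_ids$a[seq_len(ns)],
                               species_b = gene_ids$b[seq_len(ns)],
                               stringsAsFactors = FALSE)

  # deterministic gene slots: shared modules fill the front of the ortholog
  # subset, species-specific modules the front of the non-ortholog tail
  mods <- design$modules
  slot_shared <- 0L
  slot_specific <- ns
  mod_index <- vector("list", nrow(mods))
  for (i in seq_len(nrow(mods))) {
    sz <- mods$size[i]
    if (mods$shared[i]) {
      mod_index[[i]] <- slot_shared + seq_len(sz)
      slot_shared <- slot_shared + sz
    } else {
      mod_index[[i]] <- slot_specific + seq_len(sz)
      slot_specific <- slot_specific + sz
    }
  }

  # per-gene factor correlations r_g = sqrt(rho) * v_g with v spread as wide
  # as the mean-correlation constraint allows (hub gradient); population
  # pairwise correlation is r_g * r_h, whose mean over genes is rho exactly.
  # Loadings are identical across species for shared (ortholog-matched)
  # modules.
  jitter_loading <- function(sz, rho) {
    if (rho >= 1) return(rep(1, sz))
    if (rho <= 0) return(rep(0, sz))
    vmax <- min(1.15, 0.995 / sqrt(rho))
    sqrt(rho) * stats::runif(sz, 2 - vmax, vmax)
  }
  loadings_by_mod <- lapply(seq_len(nrow(mods)), function(i)
    jitter_loading(mods$size[i], mods$within_cor[i]))

  # trait membership: random half of samples per species; shared across the
  # two species only in name
  traits <- design$trait_links

  make_species <- function(sp) {
    ids <- gene_ids[[sp]]
    samp_ids <- sprintf("s%s_%02d_%03d", toupper(sp), study_of, seq_len(n_samp))
    x <- matrix(stats::rnorm(design$n_genes * n_samp, sd = design$noise_sd),
                design$n_genes, n_samp, dimnames = list(ids, samp_ids))
    truth_mod <- stats::setNames(rep("background", design$n_genes), ids)
    truth_load <- stats::setNames(rep(0, design$n_genes), ids)

    trait_table <- matrix(0L, n_samp, max(1L, nrow(traits)),
                          dimnames = list(samp_ids,
                                          if (nrow(traits)) traits$trait else "none"))
    member_sets <- lapply(seq_len(nrow(traits)), function(t)
      sort(sample.int(n_samp, n_samp %/% 2)))
    for (t in seq_len(nrow(traits)))
      trait_table[member_sets[[t]], t] <- 1L
    if (nrow(traits) == 0) trait_table <- trait_table[, 0, drop = FALSE]

    markers <- character(0)
    for (i in seq_len(nrow(mods))) {
      sz <- mods$size[i]
      rho <- mods$within_cor[i]
      idx <- mod_index[[i]]
      lam <- if (mods$shared[i]) loadings_by_mod[[i]] else
        jitter_loading(sz, rho)
      f <- stats::rnorm(n_samp)
      # trait shifts act on the module's latent factor
      for (t in seq_len(nrow(traits))) {
        if (traits$module[t] == mods$label[i])
          f[member_sets[[t]]] <- f[member_sets[[t]]] + traits$effect[t]
      }
      sigma <- design$noise_sd * sqrt(1 - lam^2)  # per-gene residual scale
      x[idx, ] <- lam %o% f +
        matrix(stats::rnorm(sz * n_samp), sz, n_samp) * sigma
      # direct marker shift: first gene of a trait-linked module
      for (t in seq_len(nrow(traits))) {
        if (traits$module[t] == mods$label[i]) {
          mk <- idx[1L]
          x[mk, member_sets[[t]]] <- x[mk, member_sets[[t]]] + traits$effect[t]
          markers <- c(markers, stats::setNames(ids[mk], traits$trait[t]))
        }
      }
      truth_mod[idx] <- mods$label[i]
      truth_load[idx] <- lam
    }

    # additive per-study, per-gene batch offsets
    if (design$batch_shift_sd > 0) {
      for (st in seq_along(design$samples_per_study)) {
        off <- stats::rnorm(design$n_genes, sd = design$batch_shift_sd)
        x[, study_of == st] <- x[, study_of == st] + off
      }
    }
    list(x = x, modules = truth_mod, loadings = truth_load,
         trait_table = trait_table, markers = markers,
         study = stats::setNames(study_of, samp_ids))
  }

  a <- make_species("a")
  b <- make_species("b")

  class_labels <- NULL
  if (nrow(traits) > 0) {
    member <- a$trait_table[, traits$trait[1L]] == 1L
    class_labels <- stats::setNames(
      ifelse(member, "disease", "healthy"), rownames(a$trait_table))
  }

  list(expr = list(a = a$x, b = b$x),
       study = list(a = a$study, b = b$study),
       truth = list(modules = list(a = a$modules, b = b$modules),
                    loadings = list(a = a$loadings, b = b$loadings),
                    ortholog_table = ortholog_table,
                    trait_table = list(a = a$trait_table, b = b$trait_table),
                    class_labels = class_labels,
                    markers = list(a = a$markers, b = b$markers)))
}

#' Generate a probe-to-gene table with known collapse winners
#'
#' Fixture generator for the max-mean probe collapse rule: each gene gets
#' `probes_per_gene` probes with deterministic mean offsets 0, 1, 2, ... so
#' the expected winner of max-mean collapsing (the highest-offset probe) is
#' known in advance.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param probes_per_gene probes per gene (>= 1).
#' @param seed seed controlling probe id suffix shuffling.
#' @return data.frame with columns `probe_id`, `gene_id`, `offset`.
#' @export
simulate_probe_table <- function(gene_ids, probes_per_gene = 3, seed = 1) {
  if (length(gene_ids) == 0) stop("gene_ids must be non-empty")
  if (probes_per_gene < 1) stop("probes_per_gene must be >= 1")
  set.seed(seed)
  tab <- do.call(rbind, lapply(gene_ids, function(g) {
    ord <- sample.int(probes_per_gene)  # offset order varies per gene
    data.frame(probe_id = sprintf("%s_at%d", g, seq_len(probes_per_gene)),
               gene_id = g,
               offset = (ord - 1),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab
}

#' Expand a gene expression matrix into probe-level rows
#'
#' Each probe row equals its gene's expression plus the probe's recorded
#' mean offset (plus optional probe noise), so collapsing by maximum mean
#' must recover the highest-offset probe.
#'
#' @param expr genes x samples matrix.
#' @param probe_table output of [simulate_probe_table()].
#' @param probe_noise_sd sd of probe-level noise (0 = deterministic).
#' @param seed seed used when `probe_noise_sd > 0`.
#' @return probes x samples matrix.
#' @export
probe_expression <- function(expr, probe_table, probe_noise_sd = 0, seed = 1) {
  .check_expression_matrix(expr)
  missing <- setdiff(probe_table$gene_id, rownames(expr))
  if (length(missing))
    stop("probe_table references genes absent from expr")
  out <- expr[probe_table$gene_id, , drop = FALSE] + probe_table$offset
  rownames(out) <- probe_table$probe_id
  if (probe_noise_sd > 0) {
    set.seed(seed)
    out <- out + matrix(stats::rnorm(length(out), sd = probe_noise_sd),
                        nrow(out), ncol(out))
  }
  out
}
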