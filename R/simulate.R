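#' Configuration for the synthetic experiment generator
#'
#' The generator emulates the structure of a multi-group tumor vs. cell-line
#' vs. control RNA-seq study: 7 disease groups plus a control group with
#' unequal replication (37 libraries by default), three gene biotypes with
#' different baseline expression, negative-binomial counts with library-size
#' variation, planted group-specific log2 fold changes, and gene sets built
#' around planted pathway-profile archetypes.
#'
#' Counts are drawn NB with mean `s_j * mu_g * 2^beta_gG(j)` and variance
#' `mean + alpha_g * mean^2`.  Baseline means `mu_g` are log-normal per
#' biotype (non-coding biotypes lower by default), dispersions `alpha_g` are
#' gamma, library-size factors `s_j` log-normal around 1.
#'
#' Planted differential expression is organized into pools that downstream
#' modules are designed to recover: a "core" of genes moved in the same
#' direction in every group, a cell-line-only core (moved in the five
#' cell-line groups, untouched in the two tumor groups), a few deliberately
#' discordant genes (opposite sign in one group), and disjoint per-group
#' exclusive genes.  Fold-change magnitudes are uniform on
#' `fc_range` with random sign (sign fixed per gene within a pool).
#'
#' Pathways are assembled from those pools so that each archetype has an
#' unambiguous expected net-expression sign pattern: `negative_all`,
#' `positive_all`, `near_zero`, and `cell_line_only` (negative in cell-line
#' groups, zero in tumor groups).
#'
#' @param n_genes named integer vector of gene counts per biotype.
#' @param replicates named integer vector of replicates per non-control
#'   group; defaults mirror the study design (12, 4, 5, 5, 1, 2, 4).
#' @param n_control control replicates (default 4).
#' @param control_group label for the control group.
#' @param baseline_meanlog,baseline_sdlog per-biotype log-normal parameters
#'   of baseline means.
#' @param dispersion_shape,dispersion_rate gamma parameters of per-gene NB
#'   dispersion (defaults give mean alpha = 0.1).
#' @param libsize_sdlog sd of log library-size factors (centered on 1).
#' @param de_fraction fraction of genes planted as differentially expressed
#'   overall.
#' @param core_fraction fraction of planted genes shared (same sign) across
#'   all groups.
#' @param cellline_fraction fraction of planted genes moved only in
#'   cell-line groups.
#' @param n_discordant number of genes planted with opposite sign in one
#'   group ("GL1") versus all others.
#' @param fc_range magnitude range of planted |log2 fold change|.
#' @param n_pathways total number of gene sets to emit.
#' @param pathway_size_range integer range of pathway sizes.
#' @param archetype_weights named numeric weights over the four archetypes.
#' @param seed integer seed; identical seeds give identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = c(protein_coding = 2000L, miRNA = 150L,
                                   lncRNA = 600L),
                       replicates = c(B_lymphoma = 12L, probT_lymphoma = 4L,
                                      CLBL1 = 5L, CLBL1M = 5L, GL1 = 1L,
                                      CL1 = 2L, OSW = 4L),
                       n_control = 4L,
                       control_group = "control",
                       baseline_meanlog = c(protein_coding = log(150),
                                            miRNA = log(20), lncRNA = log(8)),
                       baseline_sdlog = c(protein_coding = 1.3,
                                          miRNA = 1.3, lncRNA = 1.3),
                       dispersion_shape = 2, dispersion_rate = 20,
                       libsize_sdlog = 0.2,
                       de_fraction = 0.10,
                       core_fraction = 0.20,
                       cellline_fraction = 0.15,
                       n_discordant = 2L,
                       fc_range = c(0.5, 5),
                       n_pathways = 40L,
                       pathway_size_range = c(20L, 60L),
                       archetype_weights = c(negative_all = 0.2,
                                             positive_all = 0.2,
                                             near_zero = 0.4,
                                             cell_line_only = 0.2),
                       seed = 1L) {
  stopifnot(all(n_genes >= 0), all(replicates >= 1L), n_control >= 1L,
            de_fraction >= 0, de_fraction <= 1,
            core_fraction >= 0, core_fraction <= 1,
            cellline_fraction >= 0, cellline_fraction <= 1,
            core_fraction + cellline_fraction <= 1,
            dispersion_shape > 0, dispersion_rate > 0, libsize_sdlog >= 0,
            length(fc_range) == 2L, fc_range[1L] > 0,
            fc_range[2L] >= fc_range[1L],
            pathway_size_range[1L] >= 1L,
            all(archetype_weights >= 0), sum(archetype_weights) > 0)
  if (any(replicates < 1L)) stop("replicate counts must be >= 1")
  structure(as.list(environment()), class = "sim_config")
}

# Five of the seven default groups are immortalized cell lines; the planted
# cell-line-only pool moves exactly these.
cell_line_groups <- function(groups) {
  intersect(c("CLBL1", "CLBL1M", "GL1", "CL1", "OSW"), groups)
}

#' Simulate a complete synthetic experiment
#'
#' Draws a count matrix, group design, gene-set collection and the ground
#' truth (planted log2 fold changes per gene per group, pathway archetype
#' labels, true size factors) from a [sim_config()].
#'
#' @param config a [sim_config()].
#' @return a list with elements `counts` ([count_matrix()]), `design`
#'   ([group_design()]), `gene_sets` (`gene_set_collection`), and `truth`
#'   (list with `beta` gene x group matrix of planted log2 fold changes,
#'   `archetype` per-pathway labels, `size_factors` per sample).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  groups <- names(cfg$replicates)
  G <- sum(cfg$n_genes)
  biotype <- rep(names(cfg$n_genes), times = cfg$n_genes)
  gene_ids <- sprintf("gene%05d", seq_len(G))
  names(biotype) <- gene_ids

  # design
  sample_groups <- c(rep(groups, times = cfg$replicates),
                     rep(cfg$control_group, cfg$n_control))
  sample_ids <- paste0(sample_groups, "_",
                       stats::ave(seq_along(sample_groups), sample_groups,
                                  FUN = seq_along))
  design <- group_design(stats::setNames(sample_groups, sample_ids),
                         cfg$control_group, group_order = groups,
                         allow_single_control = cfg$n_control < 2L)

  # gene-level parameters
  mu <- stats::rlnorm(G, meanlog = cfg$baseline_meanlog[biotype],
                      sdlog = cfg$baseline_sdlog[biotype])
  alpha <- stats::rgamma(G, shape = cfg$dispersion_shape,
                         rate = cfg$dispersion_rate)
  sf <- stats::rlnorm(length(sample_ids), meanlog = 0,
                      sdlog = cfg$libsize_sdlog)
  sf <- sf / exp(mean(log(sf)))  # geometric mean 1
  names(sf) <- sample_ids

  # planted effects: partition the DE budget into pools
  beta <- matrix(0, G, length(groups),
                 dimnames = list(gene_ids, groups))
  pools <- list(core_up = character(0), core_down = character(0),
                cellline_up = character(0), cellline_down = character(0),
                discordant = character(0), null = gene_ids)
  n_de <- round(cfg$de_fraction * G)
  if (n_de > 0) {
    de_genes <- sample(gene_ids, n_de)
    n_core <- round(cfg$core_fraction * n_de)
    n_cl <- round(cfg$cellline_fraction * n_de)
    n_disc <- min(cfg$n_discordant, n_de - n_core - n_cl)
    idx <- 0L
    take <- function(n) {
      out <- de_genes[seq_len(n) + idx]
      idx <<- idx + n
      out
    }
    core <- take(n_core)
    pools$core_up <- core[seq_len(ceiling(n_core / 2))]
    pools$core_down <- setdiff(core, pools$core_up)
    cl <- take(n_cl)
    pools$cellline_up <- cl[seq_len(ceiling(n_cl / 2))]
    pools$cellline_down <- setdiff(cl, pools$cellline_up)
    pools$discordant <- take(n_disc)
    exclusive <- if (idx < n_de) de_genes[(idx + 1):n_de] else character(0)
    excl_group <- rep_len(groups, length(exclusive))

    draw_mag <- function(n) stats::runif(n, cfg$fc_range[1L], cfg$fc_range[2L])
    cl_groups <- cell_line_groups(groups)
    beta[pools$core_up, ] <- draw_mag(length(pools$core_up))
    beta[pools$core_down, ] <- -draw_mag(length(pools$core_down))
    beta[pools$cellline_up, cl_groups] <- draw_mag(length(pools$cellline_up))
    beta[pools$cellline_down, cl_groups] <-
      -draw_mag(length(pools$cellline_down))
    if (n_disc > 0) {
      # up everywhere except one cell-line group, where the sign flips
      flip <- if (length(cl_groups)) cl_groups[1L] else groups[1L]
      beta[pools$discordant, ] <- draw_mag(length(pools$discordant))
      beta[pools$discordant, flip] <- -draw_mag(length(pools$discordant))
    }
    if (length(exclusive)) {
      sgn <- sample(c(-1, 1), length(exclusive), replace = TRUE)
      beta[cbind(exclusive, excl_group)] <- sgn * draw_mag(length(exclusive))
    }
    pools$null <- setdiff(gene_ids, de_genes)
  }

  # counts: NB(mean = s_j * mu_g * 2^beta, var = mean + alpha * mean^2)
  beta_full <- cbind(beta, matrix(0, G, 1,
                                  dimnames = list(gene_ids,
                                                  cfg$control_group)))
  mean_mat <- outer(mu, sf) * 2^beta_full[, sample_groups, drop = FALSE]
  counts <- matrix(stats::rnbinom(length(mean_mat), mu = mean_mat,
                                  size = rep(1 / pmax(alpha, 1e-12),
                                             length(sample_ids))),
                   nrow = G, dimnames = list(gene_ids, sample_ids))
  cm <- count_matrix(counts, biotype = biotype)

  # pathways built from the pools so each archetype has a known sign pattern
  n_arch <- round(cfg$n_pathways * cfg$archetype_weights /
                    sum(cfg$archetype_weights))
  n_arch[1L] <- cfg$n_pathways - sum(n_arch[-1L])
  archetype <- rep(names(n_arch), times = pmax(n_arch, 0L))
  if (length(archetype) < cfg$n_pathways) {
    archetype <- c(archetype,
                   rep("near_zero", cfg$n_pathways - length(archetype)))
  }
  archetype <- archetype[seq_len(cfg$n_pathways)]
  sets <- vector("list", cfg$n_pathways)
  set_ids <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  sizes <- sample(cfg$pathway_size_range[1L]:cfg$pathway_size_range[2L],
                  cfg$n_pathways, replace = TRUE)
  pick <- function(pool, n) {
    if (!length(pool)) return(character(0))
    sample(pool, min(n, length(pool)))
  }
  for (i in seq_len(cfg$n_pathways)) {
    m <- sizes[i]
    members <- switch(
      archetype[i],
      negative_all = c(pick(pools$core_down, ceiling(0.6 * m)),
                       pick(pools$null, m)),
      positive_all = c(pick(pools$core_up, ceiling(0.6 * m)),
                       pick(pools$null, m)),
      near_zero = pick(pools$null, m),
      cell_line_only = c(pick(pools$cellline_down, ceiling(0.6 * m)),
                         pick(pools$null, m)))
    sets[[i]] <- utils::head(unique(members), m)
  }
  names(sets) <- set_ids
  gene_sets <- structure(sets,
                         description = stats::setNames(archetype, set_ids),
                         class = "gene_set_collection")

  list(counts = cm, design = design, gene_sets = gene_sets,
       truth = list(beta = beta,
                    archetype = stats::setNames(archetype, set_ids),
                    size_factors = sf,
                    pools = pools))
}

#' Expected net-expression sign pattern of a planted archetype
#'
#' Given the truth matrix of planted log2 fold changes, computes the net
#' expression each pathway would have if every planted effect were called
#' correctly (the direction matrix `sign(beta)`), restricted to the pathway's
#' members.  Used to verify archetype recoverability.
#'
#' @param truth the `truth` element of [simulate_experiment()] output.
#' @param gene_sets the generated `gene_set_collection`.
#' @return pathway x group matrix of true net-expression values.
#' @export
true_net_expression <- function(truth, gene_sets) {
  dirs <- sign(truth$beta)
  t(vapply(gene_sets, function(members) {
    d <- dirs[members, , drop = FALSE]
    colSums(d == 1) / length(members) - colSums(d == -1) / length(members)
  }, numeric(ncol(dirs))))
}
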