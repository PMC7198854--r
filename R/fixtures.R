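# Synthetic-data generator. Emulates the statistical structure the method
# assumes: a directed scale-free reference network carrying densely
# interconnected driver modules, tumor-only correlated expression blocks
# (shared-factor construction), cohort mutation tables in which drivers are
# mutation-enriched (partly as +2/-2 copy-number events), and seed/benchmark
# gene sets. Every generator is a pure function of the config: identical
# rng_seed gives byte-identical output.

#' Fixture configuration
#'
#' Defaults describe the standard study condition used throughout the test
#' suite and the acceptance script: 300 genes, 3 planted driver modules of 10
#' genes each, tumor-only within-module correlation 0.7, 150 tumor + 150
#' normal samples, half the drivers known as seeds, driver mutation rate 0.3
#' vs background 0.02 per sample.
#'
#' @param n_genes Total genes.
#' @param n_tumor,n_normal Sample counts per condition.
#' @param n_modules Planted tumor-only correlated driver modules.
#' @param block_size Genes per module.
#' @param within_block_correlation Target pairwise Pearson correlation inside
#'   a module in the tumor condition, in (0, 1).
#' @param pa_out_links Out-links per node in the preferential-attachment
#'   reference graph (heavy-tailed out-degree).
#' @param seed_overlap Fraction of planted drivers included in the seed set.
#' @param n_decoy_seeds Non-driver genes added to the seed set.
#' @param mutation_base_rate Per-sample mutation probability, non-drivers.
#' @param driver_mutation_rate Per-sample mutation probability, drivers.
#' @param cnv_fraction Fraction of driver mutation events emitted as +2/-2
#'   copy-number calls instead of SNVs.
#' @param lowlevel_cnv_rate Rate of neutral +1/-1 copy-number noise (never
#'   counts as a mutation).
#' @param rng_seed Integer seed.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_genes = 300L, n_tumor = 150L, n_normal = 150L,
                           n_modules = 3L, block_size = 10L,
                           within_block_correlation = 0.7,
                           pa_out_links = 3L, seed_overlap = 0.5,
                           n_decoy_seeds = 10L,
                           mutation_base_rate = 0.02,
                           driver_mutation_rate = 0.3,
                           cnv_fraction = 0.3, lowlevel_cnv_rate = 0.05,
                           rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
    n_normal = as.integer(n_normal), n_modules = as.integer(n_modules),
    block_size = as.integer(block_size),
    within_block_correlation = within_block_correlation,
    pa_out_links = as.integer(pa_out_links), seed_overlap = seed_overlap,
    n_decoy_seeds = as.integer(n_decoy_seeds),
    mutation_base_rate = mutation_base_rate,
    driver_mutation_rate = driver_mutation_rate,
    cnv_fraction = cnv_fraction, lowlevel_cnv_rate = lowlevel_cnv_rate,
    rng_seed = as.integer(rng_seed)
  )
  with(cfg, {
    stopifnot(n_genes > 0, n_tumor > 0, n_normal > 0, n_modules >= 0, block_size > 0)
    stopifnot(within_block_correlation > 0, within_block_correlation < 1)
    stopifnot(seed_overlap >= 0, seed_overlap <= 1)
    rates <- c(mutation_base_rate, driver_mutation_rate, cnv_fraction, lowlevel_cnv_rate)
    stopifnot(all(rates >= 0), all(rates <= 1))
    if (n_modules * block_size > n_genes) abort("planted modules exceed the gene universe")
    if (pa_out_links >= n_genes) abort("preferential-attachment out-links must be below n_genes")
  })
  structure(cfg, class = "fixture_config")
}

fixture_genes <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

fixture_blocks <- function(cfg) {
  genes <- fixture_genes(cfg)
  lapply(seq_len(cfg$n_modules), function(b) {
    genes[((b - 1) * cfg$block_size + 1):(b * cfg$block_size)]
  })
}

#' Planted driver genes of a fixture
#'
#' @param cfg A `fixture_config`.
#' @return A `gene_set` of the module genes (the planted truth).
#' @export
fixture_drivers <- function(cfg) {
  gene_set(unlist(fixture_blocks(cfg)), name = "planted_drivers")
}

#' Synthetic directed reference network
#'
#' A preferential-attachment graph (edges oriented so early, much-cited nodes
#' carry heavy-tailed out-degree) with every planted module additionally made
#' a directed clique, so module edges are guaranteed present. No self-loops.
#'
#' @param cfg A `fixture_config`.
#' @return A `directed_network` over all fixture genes.
#' @export
make_reference_network <- function(cfg) {
  genes <- fixture_genes(cfg)
  edges <- withr::with_seed(cfg$rng_seed, {
    g <- igraph::sample_pa(cfg$n_genes, power = 1, m = cfg$pa_out_links,
                           directed = TRUE)
    igraph::as_edgelist(g, names = TRUE)
  })
  # sample_pa points new -> old; reverse so accumulating nodes gain OUT-links
  pa <- tibble(from = genes[as.integer(edges[, 2])], to = genes[as.integer(edges[, 1])])
  block_edges <- purrr::map(fixture_blocks(cfg), function(b) {
    tidyr::expand_grid(from = b, to = b) |> dplyr::filter(.data$from != .data$to)
  }) |> purrr::list_rbind()
  directed_network(dplyr::bind_rows(pa, block_edges), genes = genes)
}

shift_nonneg <- function(m) m - min(m)

#' Synthetic tumor and normal expression
#'
#' Normal condition: independent standard Gaussian noise per gene. Tumor
#' condition: genes of each planted module share a per-sample factor,
#' `x = sqrt(rho) * factor + sqrt(1 - rho) * noise`, giving pairwise
#' correlation `rho` within the module and 0 elsewhere. Both matrices are
#' shifted to be non-negative (an affine shift, which leaves every
#' correlation untouched).
#'
#' @param cfg A `fixture_config`.
#' @param net Ignored except for its gene universe; defaults to the fixture
#'   genes.
#' @return List with `tumor` and `normal` `expression_matrix` objects.
#' @export
make_expression <- function(cfg, net = NULL) {
  genes <- if (is.null(net)) fixture_genes(cfg) else net$genes
  rho <- cfg$within_block_correlation
  blocks <- fixture_blocks(cfg)
  withr::with_seed(cfg$rng_seed + 1L, {
    tumor <- matrix(rnorm(length(genes) * cfg$n_tumor), length(genes), cfg$n_tumor,
                    dimnames = list(genes, sprintf("t%04d", seq_len(cfg$n_tumor))))
    for (b in blocks) {
      f <- rnorm(cfg$n_tumor)
      tumor[b, ] <- sqrt(rho) * matrix(f, length(b), cfg$n_tumor, byrow = TRUE) +
        sqrt(1 - rho) * tumor[b, , drop = FALSE]
    }
    normal <- matrix(rnorm(length(genes) * cfg$n_normal), length(genes), cfg$n_normal,
                     dimnames = list(genes, sprintf("n%04d", seq_len(cfg$n_normal))))
    list(
      tumor = new_expression_matrix(shift_nonneg(tumor), "tumor"),
      normal = new_expression_matrix(shift_nonneg(normal), "normal")
    )
  })
}

#' Synthetic SNV and CNV tables
#'
#' Per gene and tumor sample, a Bernoulli mutation event: drivers at
#' `driver_mutation_rate`, others at `mutation_base_rate`. A
#' `cnv_fraction` share of driver events is emitted as a +2 or -2
#' copy-number call instead of an SNV (exercising the GISTIC rule);
#' additional neutral +1/-1 calls are sprinkled at `lowlevel_cnv_rate`.
#'
#' @param cfg A `fixture_config`.
#' @param drivers A `gene_set`; defaults to [fixture_drivers()].
#' @return List with binary `snv` and integer `cnv` gene-by-sample matrices.
#' @export
make_mutation_data <- function(cfg, drivers = fixture_drivers(cfg)) {
  genes <- fixture_genes(cfg)
  samples <- sprintf("t%04d", seq_len(cfg$n_tumor))
  rate <- ifelse(genes %in% drivers$genes, cfg$driver_mutation_rate, cfg$mutation_base_rate)
  withr::with_seed(cfg$rng_seed + 2L, {
    event <- matrix(rbinom(length(genes) * cfg$n_tumor, 1,
                           rep(rate, times = cfg$n_tumor)),
                    length(genes), cfg$n_tumor, dimnames = list(genes, samples))
    as_cnv <- event == 1 &
      matrix(genes %in% drivers$genes, length(genes), cfg$n_tumor) &
      matrix(runif(length(event)) < cfg$cnv_fraction, length(genes), cfg$n_tumor)
    snv <- event * (!as_cnv)
    cnv <- matrix(0L, length(genes), cfg$n_tumor, dimnames = list(genes, samples))
    cnv[as_cnv] <- sample(c(-2L, 2L), sum(as_cnv), replace = TRUE)
    lowlevel <- cnv == 0L & matrix(runif(length(cnv)) < cfg$lowlevel_cnv_rate,
                                   length(genes), cfg$n_tumor)
    cnv[lowlevel] <- sample(c(-1L, 1L), sum(lowlevel), replace = TRUE)
    storage.mode(snv) <- "double"
    list(snv = snv, cnv = cnv)
  })
}

#' Synthetic seed and benchmark gene sets
#'
#' Seeds are a `seed_overlap` fraction of the planted drivers (sampled
#' without replacement) plus `n_decoy_seeds` non-driver decoys; the benchmark
#' is the full planted-driver set.
#'
#' @param cfg A `fixture_config`.
#' @param drivers A `gene_set`; defaults to [fixture_drivers()].
#' @return List with `seeds` and `benchmark` `gene_set`s.
#' @export
make_gene_sets <- function(cfg, drivers = fixture_drivers(cfg)) {
  genes <- fixture_genes(cfg)
  withr::with_seed(cfg$rng_seed + 3L, {
    n_known <- round(cfg$seed_overlap * length(drivers$genes))
    known <- if (n_known > 0) sample(drivers$genes, n_known) else character(0)
    non_drivers <- setdiff(genes, drivers$genes)
    decoys <- if (cfg$n_decoy_seeds > 0) {
      sample(non_drivers, min(cfg$n_decoy_seeds, length(non_drivers)))
    } else character(0)
    list(
      seeds = gene_set(c(known, decoys), name = "seeds"),
      benchmark = gene_set(drivers$genes, name = "planted_drivers")
    )
  })
}

#' Generate the full synthetic input bundle
#'
#' @param cfg A `fixture_config`.
#' @return A `fixture_bundle` list: `config`, `reference`, `tumor`, `normal`,
#'   `snv`, `cnv`, `seeds`, `benchmark`, `drivers`.
#' @export
simulate_fixture <- function(cfg = fixture_config()) {
  drivers <- fixture_drivers(cfg)
  net <- make_reference_network(cfg)
  expr <- make_expression(cfg, net)
  mut <- make_mutation_data(cfg, drivers)
  sets <- make_gene_sets(cfg, drivers)
  structure(
    list(
      config = cfg, reference = net, tumor = expr$tumor, normal = expr$normal,
      snv = mut$snv, cnv = mut$cnv, seeds = sets$seeds,
      benchmark = sets$benchmark, drivers = drivers
    ),
    class = "fixture_bundle"
  )
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(
    "<fixture_bundle> %d genes, %d+%d samples, %d planted driver(s), seed %d\n",
    x$config$n_genes, x$config$n_tumor, x$config$n_normal,
    length(x$drivers$genes), x$config$rng_seed
  ))
  invisible(x)
}

write_numeric_matrix <- function(m, path) {
  df <- dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write a fixture bundle as the plain-text input files the readers expect
#'
#' Emits `tumor_expr.tsv`, `normal_expr.tsv`, `network.tsv`, `snv.tsv`,
#' `cnv.tsv`, `seeds.txt`, `benchmark.txt`, and a `config.yaml` echo.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(bundle$tumor, file.path(dir, "tumor_expr.tsv"))
  write_expression(bundle$normal, file.path(dir, "normal_expr.tsv"))
  write_network(bundle$reference, file.path(dir, "network.tsv"))
  write_numeric_matrix(bundle$snv, file.path(dir, "snv.tsv"))
  write_numeric_matrix(bundle$cnv, file.path(dir, "cnv.tsv"))
  write_gene_set(bundle$seeds, file.path(dir, "seeds.txt"))
  write_gene_set(bundle$benchmark, file.path(dir, "benchmark.txt"))
  yaml::write_yaml(unclass(bundle$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
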