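#' Specify a synthetic miRNA/gene/disease fixture
#'
#' Describes a synthetic pair of source mappings (miRNA -> gene and
#' gene -> disease) with controllable size, density and planted structure, so
#' the whole pipeline can be exercised without any database download.
#' Background edges are independent Bernoulli draws at the stated densities;
#' planted structures are overlaid on top (edges are only ever added, so the
#' densities are lower bounds). Generation is a pure function of the spec,
#' seed included.
#'
#' Entity names mimic real nomenclature: miRNAs `hsa-miR-<k>-5p`/`-3p`
#' (alternating arms, so arm-suffix regex queries are exercised), genes
#' `GENE<k>`, diseases `Disease <k>`.
#'
#' @param n_mirnas,n_genes,n_diseases Layer sizes.
#' @param mirna_gene_density,gene_disease_density Bernoulli edge
#'   probabilities, in (0, 1).
#' @param hub_fraction If non-`NULL`, plant a hub: the first miRNA is
#'   connected to this fraction of all genes.
#' @param query_size If non-`NULL`, plant an enriched disease: `query_size`
#'   miRNAs are sampled as a query set and the first disease's gene set is
#'   extended to contain every gene they target, so that disease is
#'   associated with the full query after the merge (the `b = 0`, infinite
#'   odds ratio situation).
#' @param clique_sizes If non-`NULL`, an integer vector of block sizes; each
#'   block of miRNAs is given an identical dedicated gene set wired to a
#'   dedicated disease set, producing blocks with near-identical disease
#'   associations (high-overlap cliques in the pairwise network).
#' @param clique_genes,clique_diseases Genes/diseases dedicated to each
#'   planted block.
#' @param seed Mandatory RNG seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_mirnas = 100, n_genes = 600, n_diseases = 80,
                         mirna_gene_density = 0.005,
                         gene_disease_density = 0.01,
                         hub_fraction = NULL, query_size = NULL,
                         clique_sizes = NULL, clique_genes = 8,
                         clique_diseases = 12, seed) {
  if (missing(seed)) abort("fixture_spec: a seed is mandatory")
  stopifnot(
    n_mirnas >= 1, n_genes >= 1, n_diseases >= 1,
    mirna_gene_density > 0, mirna_gene_density <= 1,
    gene_disease_density > 0, gene_disease_density <= 1
  )
  if (!is.null(hub_fraction)) stopifnot(hub_fraction > 0, hub_fraction <= 1)
  if (!is.null(query_size)) stopifnot(query_size >= 1, query_size <= n_mirnas)
  structure(
    list(
      n_mirnas = n_mirnas, n_genes = n_genes, n_diseases = n_diseases,
      mirna_gene_density = mirna_gene_density,
      gene_disease_density = gene_disease_density,
      hub_fraction = hub_fraction, query_size = query_size,
      clique_sizes = clique_sizes, clique_genes = clique_genes,
      clique_diseases = clique_diseases, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

fixture_names <- function(spec) {
  k <- seq_len(spec$n_mirnas)
  list(
    mirnas = sprintf("hsa-miR-%04d-%s", k, ifelse(k %% 2 == 1, "5p", "3p")),
    genes = sprintf("GENE%04d", seq_len(spec$n_genes)),
    diseases = sprintf("Disease %04d", seq_len(spec$n_diseases))
  )
}

bernoulli_pairs <- function(sources, targets, density) {
  hit <- which(stats::runif(length(sources) * length(targets)) < density)
  tibble(
    source = sources[(hit - 1) %% length(sources) + 1],
    target = targets[(hit - 1) %/% length(sources) + 1]
  )
}

#' Generate a synthetic fixture
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `mirna_gene` and `gene_disease` (both
#'   [assoc_map]s) and `ground_truth`, a list recording the planted hub
#'   miRNA, enriched disease, its query set, and clique memberships (each
#'   `NULL` when not planted).
#' @export
generate_fixtures <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  nm <- fixture_names(spec)
  truth <- list(hub = NULL, enriched_disease = NULL, query_set = NULL,
                cliques = NULL)
  withr::with_seed(spec$seed, {
    mg <- bernoulli_pairs(nm$mirnas, nm$genes, spec$mirna_gene_density)
    gd <- bernoulli_pairs(nm$genes, nm$diseases, spec$gene_disease_density)

    reserved <- character()
    if (!is.null(spec$hub_fraction)) {
      truth$hub <- nm$mirnas[[1]]
      reserved <- truth$hub
      hub_genes <- sample(nm$genes, max(1, round(spec$hub_fraction * spec$n_genes)))
      mg <- dplyr::bind_rows(mg, tibble(source = truth$hub, target = hub_genes))
    }
    if (!is.null(spec$query_size)) {
      truth$enriched_disease <- nm$diseases[[1]]
      truth$query_set <- sample(setdiff(nm$mirnas, reserved), spec$query_size)
      reserved <- c(reserved, truth$query_set)
      # every query miRNA needs at least one target gene
      for (m in truth$query_set) {
        if (!m %in% mg$source) {
          mg <- dplyr::bind_rows(mg, tibble(source = m,
                                            target = sample(nm$genes, 1)))
        }
      }
      qgenes <- unique(mg$target[mg$source %in% truth$query_set])
      gd <- dplyr::bind_rows(gd, tibble(source = qgenes,
                                        target = truth$enriched_disease))
    }
    if (!is.null(spec$clique_sizes)) {
      pool <- setdiff(nm$mirnas, reserved)
      stopifnot(sum(spec$clique_sizes) <= length(pool))
      members <- sample(pool, sum(spec$clique_sizes))
      truth$cliques <- split(members, rep(seq_along(spec$clique_sizes),
                                          spec$clique_sizes))
      for (i in seq_along(truth$cliques)) {
        blk <- truth$cliques[[i]]
        # dedicated genes outside the background pool, so background miRNAs
        # cannot inherit the block's disease set through a shared gene
        bg <- sprintf("CLQGENE%02d_%02d", i, seq_len(spec$clique_genes))
        bd <- sample(nm$diseases, min(spec$clique_diseases, spec$n_diseases))
        mg <- dplyr::bind_rows(mg, tidyr::expand_grid(source = blk, target = bg))
        gd <- dplyr::bind_rows(gd, tidyr::expand_grid(source = bg, target = bd))
      }
    }
  })
  if (nrow(mg) == 0 || nrow(gd) == 0) {
    abort("fixture spec produced an empty mapping; raise the densities or sizes")
  }
  list(mirna_gene = assoc_map(mg), gene_disease = assoc_map(gd),
       ground_truth = truth)
}

#' Structure-free null association database
#'
#' Generates a miRNA-disease database with associations assigned uniformly at
#' random: each disease draws its miRNA-set size as a uniform fraction of the
#' miRNA universe (`msw_range`) and fills it by uniform sampling without
#' replacement. There is no planted structure of any kind, so enrichment
#' p-values computed against random queries follow their null distribution --
#' this is the fixture for type-I-error calibration studies. The per-disease
#' degree is spread continuously so the hypergeometric support is
#' fine-grained across the database (see the methods vignette for why that
#' matters when checking uniformity of discrete p-values).
#'
#' @param n_mirnas,n_diseases Universe sizes.
#' @param msw_range Range of per-disease miRNA-set sizes, as fractions of
#'   `n_mirnas`.
#' @param seed Mandatory RNG seed.
#' @return An [assoc_db].
#' @export
null_db <- function(n_mirnas = 4000, n_diseases = 600, msw_range = c(0.3, 0.7),
                    seed) {
  if (missing(seed)) abort("null_db: a seed is mandatory")
  stopifnot(n_mirnas >= 2, n_diseases >= 1,
            msw_range[1] > 0, msw_range[2] <= 1, msw_range[1] <= msw_range[2])
  mir <- sprintf("hsa-miR-%04d-%s", seq_len(n_mirnas),
                 ifelse(seq_len(n_mirnas) %% 2 == 1, "5p", "3p"))
  dis <- sprintf("Disease %04d", seq_len(n_diseases))
  pairs <- withr::with_seed(seed, {
    k <- pmax(1, round(stats::runif(n_diseases, msw_range[1], msw_range[2]) *
                         n_mirnas))
    tibble(source = rep(dis, k),
           target = unlist(lapply(k, function(ki) sample(mir, ki))))
  })
  build_db(invert_map(assoc_map(pairs)))
}

#' Write a fixture to disk
#'
#' Writes `mirna2gene.tsv`, `gene2disease.tsv` (two-column TSVs, sorted, so
#' identical specs give byte-identical files) and `ground_truth.json`.
#'
#' @param fix Output of [generate_fixtures()].
#' @param dir Output directory.
#' @return Invisibly, the three file paths.
#' @export
write_fixtures <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("mirna2gene.tsv", "gene2disease.tsv",
                            "ground_truth.json"))
  readr::write_tsv(stats::setNames(as.data.frame(fix$mirna_gene),
                                   c("miRNA", "gene")),
                   paths[[1]], progress = FALSE)
  readr::write_tsv(stats::setNames(as.data.frame(fix$gene_disease),
                                   c("gene", "disease")),
                   paths[[2]], progress = FALSE)
  jsonlite::write_json(fix$ground_truth, paths[[3]], auto_unbox = TRUE,
                       null = "null")
  invisible(paths)
}
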