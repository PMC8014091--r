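# Fisher-exact ontology over-representation per module with Z-score
# transform, plus Manhattan/Ward co-clustering of the module x term Z
# matrix into macro-clusters.

#' Fisher exact over-representation test
#'
#' Two-tailed Fisher exact test on the 2x2 table (in module and in term /
#' in module only / in term only / neither) over a fixed background
#' universe. The direction sign is positive when the observed overlap
#' exceeds the independence expectation.
#'
#' @param module_genes,term_genes character vectors (subsets of
#'   `background`; entries outside the background are ignored).
#' @param background the gene universe.
#' @return list(p, overlap, expected, sign, table).
#' @export
fisher_overrep <- function(module_genes, term_genes, background) {
  if (length(background) == 0) config_error("background universe is empty")
  background <- unique(background)
  mg <- intersect(unique(module_genes), background)
  tg <- intersect(unique(term_genes), background)
  q <- length(intersect(mg, tg))
  tab <- matrix(c(q, length(mg) - q, length(tg) - q,
                  length(background) - length(mg) - length(tg) + q), 2, 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  expected <- length(mg) * length(tg) / length(background)
  list(p = min(p, 1), overlap = q, expected = expected,
       sign = if (q > expected) 1 else if (q < expected) -1 else 0,
       table = tab)
}

#' Z-score equivalent of a two-tailed p-value
#'
#' `Z = qnorm(p/2, lower.tail = FALSE)`, signed by the direction of the
#' effect (positive for over-representation). p = 0.05 maps to 1.96,
#' p = 1 to 0.
#'
#' @param p two-tailed p-value(s) in (0, 1].
#' @param sign direction sign(s) (+1 over-, -1 under-represented).
#' @return signed Z score(s).
#' @export
p_to_z <- function(p, sign = 1) {
  if (any(p <= 0) || any(p > 1))
    validation_error("p must lie in (0, 1]")
  stats::qnorm(p / 2, lower.tail = FALSE) * sign
}

#' Two-tailed p from a Z score
#' @param z Z score(s).
#' @return two-tailed p-value(s).
#' @export
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Module x term enrichment table
#'
#' Fisher over-representation of every annotation term in every module
#' over the background universe. A (module, term) pair is significant when
#' the signed Z exceeds `z_threshold` (over-representation only) and the
#' overlap has at least `min_overlap` gene symbols.
#'
#' @param partition module partition (or named assignment vector).
#' @param term_sets named list term -> gene symbols.
#' @param background gene universe (default: all entities in the
#'   partition).
#' @param min_overlap minimum matched symbols (default 3).
#' @param z_threshold Z cut point (default 1.96).
#' @return data.frame (EnrichmentTable): module, term, overlap, expected,
#'   fisher_p, z, significant.
#' @export
enrich_modules <- function(partition, term_sets, background = NULL,
                           min_overlap = 3, z_threshold = 1.96) {
  assign <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  if (is.null(background)) background <- names(assign)
  if (length(term_sets) == 0) config_error("no annotation terms supplied")
  mods <- sort(setdiff(unique(assign), 0L))
  out <- vector("list", length(mods) * length(term_sets))
  k <- 0L
  for (mod in mods) {
    members <- names(assign)[assign == mod]
    for (term in names(term_sets)) {
      fr <- fisher_overrep(members, term_sets[[term]], background)
      z <- p_to_z(fr$p, fr$sign)
      k <- k + 1L
      out[[k]] <- data.frame(
        module = paste0("M", mod), term = term, overlap = fr$overlap,
        expected = fr$expected, fisher_p = fr$p, z = z,
        significant = (z > z_threshold) && (fr$overlap >= min_overlap),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Z matrix from an enrichment table
#'
#' @param enrichment output of [enrich_modules()].
#' @return numeric matrix modules x terms of signed Z scores.
#' @export
enrichment_z_matrix <- function(enrichment) {
  mods <- unique(enrichment$module)
  terms <- unique(enrichment$term)
  Z <- matrix(0, length(mods), length(terms),
              dimnames = list(mods, terms))
  Z[cbind(match(enrichment$module, mods), match(enrichment$term, terms))] <-
    enrichment$z
  Z
}

#' Co-cluster the module x term Z matrix
#'
#' Hierarchical clustering of rows and columns with Manhattan (L1)
#' distance and Ward linkage, cutting the module dendrogram into `k`
#' macro-clusters of modules sharing ontology profiles.
#'
#' @param z modules x terms Z matrix.
#' @param k number of macro-clusters (default 6).
#' @return list(macro_cluster: named module -> cluster id, row_order,
#'   col_order, row_hclust, col_hclust).
#' @export
cocluster_z_matrix <- function(z, k = 6) {
  if (nrow(z) < 2 || ncol(z) < 2)
    config_error("at least 2 modules and 2 terms required")
  if (all(z == 0)) {
    warning("all-zero Z matrix: single macro-cluster")
    return(list(macro_cluster = stats::setNames(rep(1L, nrow(z)),
                                                rownames(z)),
                row_order = seq_len(nrow(z)), col_order = seq_len(ncol(z)),
                row_hclust = NULL, col_hclust = NULL))
  }
  hr <- stats::hclust(stats::dist(z, method = "manhattan"),
                      method = "ward.D")
  hcl <- stats::hclust(stats::dist(t(z), method = "manhattan"),
                       method = "ward.D")
  k <- min(k, nrow(z))
  list(macro_cluster = stats::cutree(hr, k = k),
       row_order = hr$order, col_order = hcl$order,
       row_hclust = hr, col_hclust = hcl)
}

#' Read a gene-set file
#'
#' Accepts GMT (term, description, genes...) or two-column TSV
#' (term, gene).
#'
#' @param path file path.
#' @param format "gmt" or "tsv" (guessed from the extension by default).
#' @return named list term -> gene symbols.
#' @export
read_gene_sets <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path)
    sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
    names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1)
    sets
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    split(tab[[2]], tab[[1]])
  }
}
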