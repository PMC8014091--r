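# Transition report I/O, quantifier-ion selection, peptide quantification,
# precursor m/z computation and target-list construction.

.transition_cols <- c("injection_index", "sample_id", "protein", "peptide",
                      "charge", "fragment_ion", "area")

#' Read a transition-level peak-area report
#'
#' Reads an RFC 4180 CSV with columns injection_index, sample_id, protein,
#' peptide, charge, fragment_ion, area (Skyline-style long format) and
#' validates it: all required columns present, areas numeric and
#' nonnegative, injection indices positive integers, and the
#' (injection, peptide, charge, fragment) key unique. Offending rows are
#' reported by file line number (header is line 1).
#'
#' @param path CSV file path.
#' @return validated data.frame (TransitionTable).
#' @export
read_transition_report <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.transition_cols, names(tab))
  if (length(missing))
    format_error(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  if (nrow(tab) == 0) return(tab[, .transition_cols])
  validate_transition_table(tab, line_offset = 1L)
  tab[, .transition_cols]
}

#' Validate a transition table in memory
#'
#' @param tab data.frame with the transition columns.
#' @param line_offset added to row indices in error messages (1 when the
#'   table came from a CSV with a header line).
#' @return the table, invisibly.
#' @export
validate_transition_table <- function(tab, line_offset = 0L) {
  missing <- setdiff(.transition_cols, names(tab))
  if (length(missing))
    format_error(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  line <- function(i) i + line_offset
  bad <- which(!is.finite(tab$area) | tab$area < 0)
  if (length(bad))
    validation_error(sprintf(
      "negative or non-numeric area on line(s) %s",
      paste(line(utils::head(bad, 5)), collapse = ", ")))
  bad <- which(!is.finite(tab$injection_index) | tab$injection_index < 1 |
                 tab$injection_index != round(tab$injection_index))
  if (length(bad))
    validation_error(sprintf(
      "invalid injection_index on line(s) %s",
      paste(line(utils::head(bad, 5)), collapse = ", ")))
  key <- paste(tab$injection_index, tab$peptide, tab$charge,
               tab$fragment_ion, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    validation_error(sprintf(
      "duplicate (injection, peptide, charge, fragment) key on line(s) %s",
      paste(line(utils::head(dup, 5)), collapse = ", ")))
  invisible(tab)
}

#' Write a transition table as RFC 4180 CSV
#'
#' @param tab transition table.
#' @param path output path.
#' @export
write_transition_report <- function(tab, path) {
  utils::write.csv(tab[, .transition_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Select quantifier product ions for a peptide
#'
#' Ranks a peptide's fragment ions by mean area across all injections of
#' the experiment (a stable quantifier set, as in spectral-library
#' practice) and keeps the strongest `k`, ties broken by lexicographic
#' fragment label. Between 3 and 6 quantifiers are conventional; `k`
#' defaults to 5 (the top five y-ions).
#'
#' @param tab transition table.
#' @param peptide peptide sequence to select for.
#' @param k number of quantifier ions (3-6).
#' @return character vector of fragment labels, strongest first.
#' @export
select_quantifier_ions <- function(tab, peptide, k = 5) {
  rows <- tab[tab$peptide == peptide, ]
  if (nrow(rows) == 0)
    insufficient_data_error(sprintf("peptide %s not present", peptide))
  means <- tapply(rows$area, rows$fragment_ion, mean)
  if (length(means) < 3)
    insufficient_data_error(sprintf(
      "peptide %s has only %d fragment(s); at least 3 required",
      peptide, length(means)))
  ord <- order(-means, names(means))
  names(means)[ord][seq_len(min(k, length(means)))]
}

#' Quantify peptides from quantifier-ion areas
#'
#' Peptide quantity per injection is the sum of its quantifier-ion areas
#' (the strongest `k` fragments by experiment-wide mean, per
#' [select_quantifier_ions()]). An injection where fewer than
#' `min_fragments` quantifier ions have a nonzero area yields quantity 0,
#' i.e. missing.
#'
#' @param tab transition table.
#' @param k quantifier ions per peptide.
#' @param min_fragments minimum nonzero quantifier ions per injection.
#' @return peptide-level [abundance_matrix()] (peptides x injections) with
#'   attributes `injection` (column -> injection index) and `peptide_map`
#'   (peptide -> protein).
#' @export
quantify_peptides <- function(tab, k = 5, min_fragments = 3) {
  validate_transition_table(tab)
  if (nrow(tab) == 0) insufficient_data_error("empty transition table")
  # rank fragments within peptide by mean area over injections
  pf <- paste(tab$peptide, tab$fragment_ion, sep = "\r")
  mean_by_pf <- tapply(tab$area, pf, mean)
  pf_split <- strsplit(names(mean_by_pf), "\r", fixed = TRUE)
  pf_pep <- vapply(pf_split, `[[`, "", 1)
  pf_frag <- vapply(pf_split, `[[`, "", 2)
  sel <- unlist(lapply(split(seq_along(pf_pep), pf_pep), function(idx) {
    ord <- idx[order(-mean_by_pf[idx], pf_frag[idx])]
    utils::head(ord, k)
  }), use.names = FALSE)
  keep_key <- names(mean_by_pf)[sel]
  rows <- tab[pf %in% keep_key, ]

  inj <- sort(unique(tab$injection_index))
  peptides <- sort(unique(tab$peptide))
  i <- match(rows$peptide, peptides)
  j <- match(rows$injection_index, inj)
  cell <- (j - 1L) * length(peptides) + i
  quant <- matrix(0, length(peptides), length(inj),
                  dimnames = list(peptides, as.character(inj)))
  nz <- matrix(0L, length(peptides), length(inj))
  sums <- rowsum(rows$area, cell)
  counts <- rowsum(as.integer(rows$area > 0), cell)
  at <- as.integer(rownames(sums))
  quant[at] <- sums[, 1]
  nz[at] <- counts[, 1]
  quant[nz < min_fragments] <- 0

  sample_of_inj <- tab$sample_id[match(inj, tab$injection_index)]
  colnames(quant) <- sample_of_inj
  m <- abundance_matrix(quant, level = "peptide", stages = character())
  attr(m, "injection") <- stats::setNames(inj, sample_of_inj)
  attr(m, "peptide_map") <- stats::setNames(
    tab$protein[match(peptides, tab$peptide)], peptides)
  m
}

# Monoisotopic residue masses (Da); Cys carries no fixed modification here,
# carbamidomethylation is added via `fixed_mods`.
.residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.mass_h2o <- 18.0105646863
.mass_proton <- 1.00727646688

#' Monoisotopic precursor m/z
#'
#' Computes (M + z H+)/z for a peptide sequence with fixed modifications
#' applied per residue; carbamidomethyl cysteine (+57.0215 Da) is the
#' default fixed modification.
#'
#' @param peptide character vector of uppercase residue sequences.
#' @param charge positive integer charge state(s).
#' @param fixed_mods named numeric, mass added to every occurrence of the
#'   named residue.
#' @return numeric vector of m/z values (Th).
#' @export
compute_precursor_mz <- function(peptide, charge = 2L,
                                 fixed_mods = c(C = 57.02146)) {
  if (any(charge < 1)) validation_error("charge must be at least 1")
  charge <- rep_len(as.numeric(charge), length(peptide))
  vapply(seq_along(peptide), function(i) {
    res <- strsplit(peptide[i], "")[[1]]
    unknown <- setdiff(res, names(.residue_mass))
    if (length(unknown))
      validation_error(sprintf("unknown residue(s) %s in %s",
                               paste(unknown, collapse = ","), peptide[i]))
    m <- sum(.residue_mass[res]) + .mass_h2o
    for (r in names(fixed_mods)) m <- m + fixed_mods[[r]] * sum(res == r)
    (m + charge[i] * .mass_proton) / charge[i]
  }, 1.0)
}

#' Write an instrument inclusion list
#'
#' @param targets target list data.frame.
#' @param path output CSV (peptide, charge, precursor_mz).
#' @export
write_inclusion_list <- function(targets, path) {
  utils::write.csv(targets[, c("peptide", "charge", "precursor_mz")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a PRM target list by ontology filtering
#'
#' Takes the union of gene symbols in the supplied annotation sets (e.g.
#' spliceosome / ribonucleoprotein / mRNA processing / RNA binding / snRNP
#' terms) plus an interactome list, intersects with the identified
#' proteins, and removes proteins lacking a unique peptide.
#'
#' @param identified_proteins character vector of identified symbols.
#' @param annotation_sets named list term -> gene symbols.
#' @param interactome character vector of interactome symbols.
#' @param has_unique_peptide character vector of proteins with at least one
#'   unique peptide; defaults to all identified proteins.
#' @return sorted character vector of target proteins.
#' @export
build_target_list <- function(identified_proteins, annotation_sets,
                              interactome = character(),
                              has_unique_peptide = identified_proteins) {
  if (length(annotation_sets) == 0 || all(lengths(annotation_sets) == 0))
    config_error("annotation sets are empty")
  pool <- union(unique(unlist(annotation_sets, use.names = FALSE)),
                interactome)
  sort(intersect(intersect(pool, identified_proteins), has_unique_peptide))
}
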