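#' Classify alignment columns as constant, variable, parsimony-informative
#' or singleton
#'
#' Each column is classified over its unambiguous A/C/G/T cells only (gaps
#' and ambiguity codes are ignored; a column with fewer than two such cells
#' is excluded from all counts and reported in `n_excluded`). A column with
#' one observed state is constant; with two or more states it is variable;
#' a variable column with at least two states each present in at least two
#' taxa is additionally parsimony-informative, and otherwise a singleton.
#'
#' @param aln a named character vector of equal-length (gapped) sequences,
#'   or a character matrix with one row per taxon and one column per site.
#' @return List with `n_sites`, `n_excluded`, `constant`, `variable`,
#'   `parsimony_informative`, `singleton`, and `classes` (per-column labels:
#'   `"constant"`, `"informative"`, `"singleton"` or `"excluded"`).
#' @examples
#' classify_sites(c(a = "AAT", b = "AAT", c = "ATA", d = "ATA"))
#' @export
classify_sites <- function(aln) {
  m <- as_aln_matrix(aln)
  if (nrow(m) < 2L)
    stop("alignment needs at least 2 rows", call. = FALSE)
  classes <- apply(m, 2L, function(col) {
    col <- col[col %in% DNA_BASES]
    if (length(col) < 2L) return("excluded")
    tab <- table(col)
    if (length(tab) == 1L) return("constant")
    if (sum(tab >= 2L) >= 2L) return("informative")
    "singleton"
  })
  list(n_sites = ncol(m),
       n_excluded = sum(classes == "excluded"),
       constant = sum(classes == "constant"),
       variable = sum(classes %in% c("informative", "singleton")),
       parsimony_informative = sum(classes == "informative"),
       singleton = sum(classes == "singleton"),
       classes = unname(classes))
}

as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    storage.mode(aln) <- "character"
    return(toupper(aln))
  }
  if (!is.character(aln))
    stop("alignment must be a character vector or matrix", call. = FALSE)
  if (length(unique(nchar(aln))) != 1L)
    stop("ragged alignment: rows differ in length", call. = FALSE)
  do.call(rbind, lapply(toupper(aln), function(s) seq_chars(s)))
}

#' Concatenate protein-coding genes across mitogenomes
#'
#' Extracts each requested gene on its sense strand from every genome and
#' concatenates them in a fixed order, producing the unaligned per-taxon
#' supermatrix input used for mitogenome phylogenetics (alignment itself is
#' external).
#'
#' @param genomes named list of [mitogenome] objects (names are taxon
#'   labels).
#' @param gene_order character vector of PCG names; defaults to the PCG
#'   names of the first genome in annotation order.
#' @return Named character vector of concatenated sense-strand sequences.
#' @export
concat_pcgs <- function(genomes, gene_order = NULL) {
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  if (is.null(names(genomes)))
    names(genomes) <- paste0("taxon", seq_along(genomes))
  if (is.null(gene_order)) {
    f <- genomes[[1L]]$features
    gene_order <- f$name[f$type == "PCG"]
  }
  vapply(names(genomes), function(tx) {
    g <- genomes[[tx]]
    missing <- setdiff(gene_order, g$features$name)
    if (length(missing))
      stop("taxon '", tx, "' lacks gene(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    paste(vapply(gene_order, function(nm) feature_seq(g, nm),
                 character(1)), collapse = "")
  }, character(1))
}
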