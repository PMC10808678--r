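#' shrubmf: community assembly, multifunctionality and functional trade-offs
#'
#' Tools for analysing multitrophic soil community assembly and ecosystem
#' multifunctionality along a grass -> mosaic -> shrub expansion gradient:
#' abundant/rare partitioning (MultiCoLA), null-model assembly inference
#' (\eqn{\beta}NTI, RC\eqn{_{bray}}), five multifunctionality indices, a
#' per-sample trade-off intensity, and driver attribution (VIF screening,
#' RDA, forward selection, hierarchical partitioning). A synthetic-data
#' generator emulates the 3-stage x 5-replicate study design so the whole
#' chain runs without field data.
#'
#' @useDynLib shrubmf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

TAXON_GROUPS <- c("archaea", "bacteria", "fungi", "nematodes", "protists")
STAGES <- c("grass", "mosaic", "shrub")

#' Construct a community count table
#'
#' A community table stores OTU counts with samples in rows and taxa in
#' columns, tagged with the taxonomic group it describes. Taxon column names
#' must match tip labels of the paired phylogeny.
#'
#' @param counts Non-negative integer matrix, samples x taxa, with unique
#'   row (sample) and column (taxon) names.
#' @param group One of `"archaea"`, `"bacteria"`, `"fungi"`, `"nematodes"`,
#'   `"protists"`.
#' @return A `community_table` (integer matrix with a `group` attribute).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' community_table(m, "bacteria")
#' @export
community_table <- function(counts, group) {
  group <- match.arg(group, TAXON_GROUPS)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and taxon column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids")
  if (any(is.na(counts)))
    stop("missing counts are not allowed")
  if (any(counts < 0))
    stop("negative counts are not allowed")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(counts, group = group, class = c("community_table", class(counts)))
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa (%s)\n",
              nrow(x), ncol(x), attr(x, "group")))
  invisible(x)
}

#' Read a community table from TSV or BIOM
#'
#' TSV layout: first column holds sample ids, remaining columns are taxa
#' (header row of taxon ids). BIOM files (taxa x samples, the format's
#' convention) are transposed on ingestion.
#'
#' @param path File path.
#' @param group Taxonomic group label (see [community_table()]).
#' @param format `"tsv"` or `"biom"`.
#' @return A `community_table`.
#' @export
read_community <- function(path, group, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
    if (!is.numeric(m))
      stop("non-numeric counts in ", path)
    if (any(m < 0))
      stop("negative counts in ", path)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required to read BIOM files")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
  }
  community_table(round(m), group)
}

#' Write a community table as TSV
#'
#' @param x A `community_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phylogeny (Newick)
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that validate
#' what downstream null models need: at least two tips, unique tip labels and
#' non-negative branch lengths.
#'
#' @param path Newick file path.
#' @return For `read_phylogeny`, an [ape::phylo] tree.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  validate_phylogeny(tr)
  tr
}

#' @rdname read_phylogeny
#' @param tree An [ape::phylo] tree.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (length(tree$tip.label) < 2) stop("tree needs at least 2 tips")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  invisible(tree)
}

#' Check that a community's taxa are all tips of its phylogeny
#'
#' @param table A `community_table`.
#' @param tree An [ape::phylo] tree.
#' @return `TRUE`, invisibly; errors naming missing taxa otherwise.
#' @export
check_community_tree <- function(table, tree) {
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  invisible(TRUE)
}

#' Per-sample relative abundances
#'
#' @param table A count matrix (samples x taxa).
#' @return Matrix of proportions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  tot <- rowSums(table)
  if (any(tot == 0)) stop("all-zero sample row; cannot form relative abundances")
  unclass(table) / tot
}

#' The 3-stage x 5-replicate sample design
#'
#' @param n_replicates Replicates per stage (default 5, the study design).
#' @return A data.frame with `sample_id`, `stage` (ordered factor
#'   grass < mosaic < shrub) and `replicate`.
#' @examples
#' nrow(default_sample_frame())  # 15
#' @export
default_sample_frame <- function(n_replicates = 5) {
  sample_frame(
    stage = rep(STAGES, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(STAGES))
  )
}

#' @rdname default_sample_frame
#' @param stage Character vector of stage labels.
#' @param replicate Integer replicate index within stage.
#' @param sample_id Optional explicit sample ids (default `<stage>_<rep>`).
#' @export
sample_frame <- function(stage, replicate, sample_id = NULL) {
  if (!all(stage %in% STAGES))
    stop("stage must be one of: ", paste(STAGES, collapse = ", "))
  if (length(stage) != length(replicate)) stop("length mismatch")
  if (is.null(sample_id)) sample_id <- paste(stage, replicate, sep = "_")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  data.frame(sample_id = sample_id,
             stage = factor(stage, levels = STAGES, ordered = TRUE),
             replicate = as.integer(replicate))
}

#' @rdname default_sample_frame
#' @param path TSV path with columns sample_id, stage, replicate.
#' @export
read_sample_frame <- function(path) {
  df <- utils::read.delim(path)
  need <- c("sample_id", "stage", "replicate")
  if (!all(need %in% names(df)))
    stop("sample frame needs columns: ", paste(need, collapse = ", "))
  sample_frame(df$stage, df$replicate, df$sample_id)
}

#' @rdname default_sample_frame
#' @param x A sample frame.
#' @export
write_sample_frame <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

FUNCTION_SUBCATEGORIES <- c(
  "reservoir", "productivity", "erosion regulation", "nutrient provisioning",
  "element cycling", "plant health", "water regulation", "physical context",
  "ARG control"
)

#' Build the ecosystem-function registry
#'
#' The registry enumerates every functional variable entering the
#' multifunctionality indices, with its ecosystem compartment
#' (`aboveground`/`underground`), functional subcategory, and a `reflect`
#' flag marking variables whose raw direction is "high = bad" (stoichiometric
#' ratios indicating P limitation, unprotected organic carbon and its ratio,
#' fungal pathogen loads, antibiotic resistance gene abundances); those are
#' reflected with `r(f) = -f + max(f)` before unit scaling. The shipped
#' default registry holds 208 variables: 7 aboveground and 201 underground.
#'
#' @param spec_file TSV with columns name, category, subcategory, reflect;
#'   `NULL` loads the shipped default registry.
#' @return A data.frame of class `function_registry`.
#' @examples
#' reg <- build_function_registry()
#' nrow(reg)                                  # 208
#' table(reg$category)
#' @export
build_function_registry <- function(spec_file = NULL) {
  if (is.null(spec_file))
    spec_file <- system.file("extdata", "function_registry.tsv",
                             package = "shrubmf", mustWork = TRUE)
  df <- utils::read.delim(spec_file, stringsAsFactors = FALSE)
  need <- c("name", "category", "subcategory", "reflect")
  if (!all(need %in% names(df)))
    stop("registry needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("duplicate function names in registry: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  bad <- setdiff(unique(df$category), c("aboveground", "underground"))
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$subcategory), FUNCTION_SUBCATEGORIES)
  if (length(bad)) stop("unknown subcategory: ", paste(bad, collapse = ", "))
  df$reflect <- as.logical(df$reflect)
  if (any(is.na(df$reflect))) stop("reflect must be TRUE/FALSE")
  class(df) <- c("function_registry", "data.frame")
  df
}

#' Construct a function matrix
#'
#' Samples x functional-variable values paired with their registry. Columns
#' must match the registry exactly (same names, same order after matching);
#' missing values are an ingestion error because reflection and unit scaling
#' are maximum-dependent.
#'
#' @param values Numeric matrix, samples x functions, with sample row names
#'   and function column names.
#' @param registry A `function_registry` (default: shipped registry).
#' @return A `function_matrix` (numeric matrix with a `registry` attribute).
#' @export
function_matrix <- function(values, registry = build_function_registry()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have sample row names and function column names")
  if (!setequal(colnames(values), registry$name))
    stop("function columns do not match the registry (",
         ncol(values), " columns vs ", nrow(registry), " registered)")
  values <- values[, registry$name, drop = FALSE]
  if (any(is.na(values)))
    stop("missing function values are an ingestion error")
  structure(values, registry = registry,
            class = c("function_matrix", class(values)))
}

#' @export
print.function_matrix <- function(x, ...) {
  reg <- attr(x, "registry")
  cat(sprintf("function_matrix: %d samples x %d functions (%d aboveground, %d underground)\n",
              nrow(x), ncol(x), sum(reg$category == "aboveground"),
              sum(reg$category == "underground")))
  invisible(x)
}

#' Read / write a function matrix (TSV, samples in rows)
#'
#' @param path TSV path; first column sample ids, header of function names.
#' @param registry Registry to validate against.
#' @return A `function_matrix`.
#' @export
read_function_matrix <- function(path, registry = build_function_registry()) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  function_matrix(as.matrix(df), registry)
}

#' @rdname read_function_matrix
#' @param x A `function_matrix`.
#' @export
write_function_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Columns of a function matrix belonging to a scope
#'
#' @param registry A `function_registry`.
#' @param scope `"aboveground"`, `"underground"` or `"entire"`.
#' @return Character vector of function names in the scope.
#' @export
scope_functions <- function(registry, scope = c("entire", "aboveground", "underground")) {
  scope <- match.arg(scope)
  if (scope == "entire") registry$name
  else registry$name[registry$category == scope]
}
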