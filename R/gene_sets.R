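#' Construct a gene set
#'
#' A `gene_set` is a named, ordered collection of unique gene symbols.
#' Symbols are matched case-insensitively throughout the package (mixed
#' species conventions such as `Col1a1` vs `COL1A1` are the norm when rat or
#' mouse signatures are mapped to human orthologs), but the original case is
#' preserved for output. Duplicates after case-folding are collapsed, keeping
#' the first spelling, with a warning.
#'
#' @param name Short identifier string.
#' @param genes Character vector of gene symbols; must be non-empty.
#' @param description Free-text description (default `""`).
#' @return An object of class `gene_set` with elements `name`, `description`
#'   and `genes`.
#' @examples
#' gs <- gene_set("HSC_UP", c("COL1A1", "ACTA2", "PDGFRB"))
#' length(gs$genes)
#' @export
gene_set <- function(name, genes, description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) == 0L) {
    stop("gene set '", name, "' is empty; a gene set needs at least one gene")
  }
  dup <- duplicated(casefold(genes))
  if (any(dup)) {
    warning(sprintf("gene set '%s': %d duplicate symbol(s) after case-folding collapsed",
                    name, sum(dup)))
    genes <- genes[!dup]
  }
  structure(list(name = name, description = as.character(description)[1L],
                 genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes (%s%s)\n", x$name, length(x$genes),
              paste(utils::head(x$genes, 5L), collapse = ", "),
              if (length(x$genes) > 5L) ", ..." else ""))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Lines starting with `#` and
#' blank lines are ignored. Duplicate symbols within a set are collapsed
#' case-insensitively with a warning; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_set] objects, in file order.
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(lines) & !startsWith(lines, "#")
  sets <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d in '%s': %d field(s), need >= 3 (name, description, genes...)",
                   i, path, length(fields)))
    }
    gs <- gene_set(fields[1L], fields[-(1:2)], description = fields[2L])
    if (gs$name %in% names(sets)) {
      stop(sprintf("duplicate gene set name '%s' in '%s' (line %d)", gs$name, path, i))
    }
    sets[[gs$name]] <- gs
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set` or list of `gene_set` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(gs) {
    paste(c(gs$name, gs$description, gs$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Case-insensitive membership/index helpers used across modules.
fold <- function(x) casefold(as.character(x))

match_fold <- function(x, table) match(fold(x), fold(table))
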