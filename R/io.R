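#' Read a gene-by-sample count matrix
#'
#' Counts are stored genes-in-rows with the first column holding gene
#' identifiers and the header row holding sample identifiers (the dominant
#' repository convention), or as MatrixMarket `.mtx` with sibling
#' `<stem>.rownames` / `<stem>.colnames` files (one identifier per line).
#'
#' @param path Path to the counts file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`. Defaults from the file
#'   extension.
#' @return An integer matrix with gene rownames and sample colnames. All
#'   entries are validated to be non-negative integers; the offending cell is
#'   named otherwise.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     abort(sprintf("Cannot infer counts format from '%s'.", path)))
  }
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rn <- readLines(paste0(stem, ".rownames"))
    cn <- readLines(paste0(stem, ".colnames"))
    dimnames(m) <- list(rn, cn)
  } else {
    delim <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, sep = delim, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  storage.mode(m) <- "double"
  assert_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix
#'
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param format `"tsv"`, `"csv"` or `"mtx"` (MTX writes sibling
#'   `.rownames`/`.colnames` files).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  assert_counts(counts)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(counts), paste0(stem, ".rownames"))
    writeLines(colnames(counts), paste0(stem, ".colnames"))
  } else {
    delim <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read or write a sample metadata table
#'
#' Tab-separated with columns `sample_id`, `mission`, `subset_id`,
#' `condition` (flight/ground) and any further covariates.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_samples <- function(path) {
  df <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE))
  assert_samples(df)
}

#' @rdname read_samples
#' @param samples Sample tibble to write.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate
#' members within a set are dropped with a warning.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors of member genes, with a
#'   `descriptions` attribute; class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    abort(sprintf("GMT parse error at line %d: fewer than 3 tab-separated fields.",
                  short[1]))
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) abort("Duplicate gene-set names in GMT.")
  descr <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn(sprintf("Duplicate members in set '%s' deduplicated.", f[[1]]))
      members <- unique(members)
    }
    members
  })
  gene_set_collection(setNames(sets, names_), descriptions = setNames(descr, names_))
}

#' Construct a gene-set collection
#'
#' @param sets Named list of non-empty character vectors.
#' @param descriptions Optional named character vector of descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(!nzchar(names(sets)))) {
    abort("Gene sets must carry unique non-empty names.")
  }
  if (any(lengths(sets) == 0L)) abort("Gene sets must be non-empty.")
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d..%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection` to write.
#' @export
write_gmt <- function(collection, path) {
  descr <- attr(collection, "descriptions") %||% setNames(rep("", length(collection)),
                                                          names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descr[[nm]], collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a signed regulator knowledge base
#'
#' Tab-separated columns `regulator`, `target`, `sign` with sign in
#' \{+1, -1\}, meaning the regulator's activity increases (+1) or decreases
#' (-1) the target's expression. Duplicate (regulator, target) pairs are
#' rejected.
#'
#' @param path File path.
#' @return A tibble with columns `regulator`, `target`, `sign`.
#' @export
read_kb <- function(path) {
  df <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE))
  validate_kb(df)
}

validate_kb <- function(kb) {
  kb <- as_tibble(kb)
  need <- c("regulator", "target", "sign")
  if (!all(need %in% names(kb))) {
    abort("Knowledge base needs columns regulator, target, sign.")
  }
  if (!all(kb$sign %in% c(-1, 1))) abort("Knowledge-base signs must be +1 or -1.")
  if (anyDuplicated(kb[c("regulator", "target")])) {
    abort("Duplicate (regulator, target) pairs in knowledge base.")
  }
  kb
}

#' Read an ortholog mapping table
#'
#' Tab-separated columns `source`, `target`; one source gene may map to many
#' target genes. Fully duplicated rows are rejected.
#'
#' @param path File path.
#' @return A tibble with columns `source`, `target`.
#' @export
read_ortholog_map <- function(path) {
  df <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE))
  if (!all(c("source", "target") %in% names(df))) {
    abort("Ortholog map needs columns source, target.")
  }
  if (anyDuplicated(df)) abort("Fully duplicated rows in ortholog map.")
  df
}

#' Map genes through an ortholog table
#'
#' Returns the union of all targets of the input genes in first-seen order
#' (one-to-many mappings are expanded); unmapped genes are dropped with a
#' message.
#'
#' @param genes Character vector of source gene ids.
#' @param map Ortholog map tibble (`source`, `target`).
#' @return Character vector of mapped target ids (possibly empty).
#' @export
map_orthologs <- function(genes, map) {
  hit <- map[map$source %in% genes, , drop = FALSE]
  # preserve input order, then map order within a source
  hit <- hit[order(match(hit$source, genes)), , drop = FALSE]
  unmapped <- setdiff(genes, map$source)
  if (length(unmapped)) {
    inform(sprintf("%d gene(s) had no ortholog and were dropped.", length(unmapped)))
  }
  unique(hit$target)
}
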