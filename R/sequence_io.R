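# Protein FASTA, cluster-table and COG-table input/output.
#
# A proteome is a plain S3 list: genome_id, group, pressure_opt and a
# records data.frame (protein_id, description, sequence). Sequences are kept
# as uppercase character strings over the 20 standard amino acids plus the
# ambiguity/rare codes X, B, Z, J, U, O.

#' Construct a proteome object
#'
#' @param genome_id single genome identifier.
#' @param group group label, `"piezophile"` or `"piezosensitive"`.
#' @param records data.frame with columns `protein_id`, `description`,
#'   `sequence`.
#' @param pressure_opt optional optimal growth pressure (MPa).
#' @return An object of class `proteome`.
#' @export
proteome <- function(genome_id, group, records, pressure_opt = NA_real_) {
  group <- match.arg(group, GROUP_LEVELS)
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("protein_id", "sequence") %in% names(records)))
  if (is.null(records$description)) records$description <- ""
  if (anyDuplicated(records$protein_id)) {
    stop("duplicate protein_id in genome '", genome_id, "': ",
         records$protein_id[duplicated(records$protein_id)][1L])
  }
  validate_sequences(records$sequence, records$protein_id)
  structure(list(genome_id = genome_id, group = group,
                 pressure_opt = pressure_opt,
                 records = records[, c("protein_id", "description", "sequence")]),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("proteome", x$genome_id, sprintf("(%s)", x$group), "-",
      nrow(x$records), "proteins\n")
  invisible(x)
}

validate_sequences <- function(sequences, ids) {
  if (any(!nzchar(sequences))) {
    stop("empty sequence for record ", ids[!nzchar(sequences)][1L])
  }
  legal <- paste0(c(AA20, AA_AMBIGUOUS), collapse = "")
  bad <- regexpr(sprintf("[^%s]", legal), sequences)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal character '", substr(sequences[i], bad[i], bad[i]),
         "' in record ", ids[i])
  }
  invisible(TRUE)
}

#' Read a protein FASTA file as a proteome
#'
#' The token before the first whitespace in each header becomes the
#' `protein_id`; the remainder is kept as `description`. Letters are
#' uppercased and a single terminal `*` (stop) is stripped. Any character
#' outside the 20 standard amino acids and the ambiguity codes X, B, Z, J,
#' U, O is an error naming the offending record and character.
#'
#' @param path FASTA file path.
#' @inheritParams proteome
#' @return A [proteome] object.
#' @export
read_proteome <- function(path, genome_id, group, pressure_opt = NA_real_) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  protein_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- toupper(as.character(set))
  sequence <- sub("\\*$", "", sequence)
  proteome(genome_id, group,
           data.frame(protein_id = unname(protein_id),
                      description = unname(description),
                      sequence = unname(sequence),
                      stringsAsFactors = FALSE),
           pressure_opt = pressure_opt)
}

#' Write a proteome as FASTA
#'
#' @param x a [proteome].
#' @param path output file path.
#' @export
write_proteome <- function(x, path) {
  stopifnot(inherits(x, "proteome"))
  set <- Biostrings::BStringSet(x$records$sequence)
  names(set) <- ifelse(nzchar(x$records$description),
                       paste(x$records$protein_id, x$records$description),
                       x$records$protein_id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a gene-cluster table
#'
#' @param clusters named list: `cluster_id -> named list(genome_id ->
#'   character vector of protein ids)`.
#' @return An object of class `cluster_table`.
#' @export
cluster_table <- function(clusters) {
  if (anyDuplicated(names(clusters))) {
    stop("duplicate cluster_id: ",
         names(clusters)[duplicated(names(clusters))][1L])
  }
  structure(list(clusters = clusters), class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("cluster_table with", length(x$clusters), "clusters\n")
  invisible(x)
}

#' Read a gene-cluster table
#'
#' Minimal tab-separated format, one row per cluster: the cluster id
#' followed by `genome_id:protein_id` member tokens. This stands in for the
#' output of upstream ortholog clustering (TribeMCL/Roary); see
#' [roary_to_cluster_table()] for a converter.
#'
#' @param path TSV file path.
#' @return A [cluster_table].
#' @export
read_cluster_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  clusters <- list()
  for (ln in seq_along(lines)) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    cid <- parts[1L]
    if (cid %in% names(clusters)) stop("duplicate cluster_id '", cid,
                                       "' at line ", ln)
    members <- parts[-1L]
    bad <- !grepl(":", members, fixed = TRUE)
    if (any(bad)) {
      stop("malformed member token '", members[bad][1L],
           "' (missing ':') at line ", ln)
    }
    genome <- sub(":.*$", "", members)
    prot <- sub("^[^:]*:", "", members)
    clusters[[cid]] <- split(prot, genome)
  }
  cluster_table(clusters)
}

#' Write a gene-cluster table
#'
#' @param x a [cluster_table].
#' @param path output path.
#' @export
write_cluster_table <- function(x, path) {
  stopifnot(inherits(x, "cluster_table"))
  rows <- vapply(names(x$clusters), function(cid) {
    m <- x$clusters[[cid]]
    toks <- unlist(lapply(names(m), function(g) paste0(g, ":", m[[g]])),
                   use.names = FALSE)
    paste(c(cid, toks), collapse = "\t")
  }, character(1L))
  writeLines(rows, path)
  invisible(path)
}

#' Check that all cluster members exist in the supplied proteomes
#'
#' @param x a [cluster_table].
#' @param proteomes list of [proteome] objects.
#' @return `TRUE` invisibly; errors on a dangling reference.
#' @export
validate_cluster_table <- function(x, proteomes) {
  ids <- lapply(proteomes, function(p) p$records$protein_id)
  names(ids) <- vapply(proteomes, `[[`, character(1L), "genome_id")
  for (cid in names(x$clusters)) {
    m <- x$clusters[[cid]]
    for (g in names(m)) {
      if (!g %in% names(ids)) next
      missing <- setdiff(m[[g]], ids[[g]])
      if (length(missing)) {
        stop("cluster ", cid, " references unknown protein '",
             missing[1L], "' in genome ", g)
      }
    }
  }
  invisible(TRUE)
}

#' Convert a Roary gene_presence_absence.csv to the cluster-table format
#'
#' Takes the `Gene` column as cluster id and every column after the 14 fixed
#' Roary metadata columns as a genome; multiple members within one cell are
#' split on tab or semicolon.
#'
#' @param path Roary CSV path.
#' @return A [cluster_table].
#' @export
roary_to_cluster_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) <= 14L) stop("no genome columns found after Roary metadata")
  genomes <- names(df)[-(1:14)]
  clusters <- lapply(seq_len(nrow(df)), function(i) {
    m <- lapply(genomes, function(g) {
      cell <- df[[g]][i]
      if (is.na(cell) || !nzchar(cell)) character(0)
      else strsplit(cell, "[\t;]")[[1L]]
    })
    names(m) <- genomes
    m[vapply(m, length, integer(1L)) > 0L]
  })
  names(clusters) <- df[[1L]]
  cluster_table(clusters)
}

#' Construct a COG category count table
#'
#' @param counts genome x category matrix of nonnegative integer counts;
#'   column names must be standard single-letter COG categories.
#' @return An object of class `cog_table`.
#' @export
cog_table <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  bad <- setdiff(colnames(counts), COG_CATEGORIES)
  if (length(bad)) stop("unknown COG category '", bad[1L], "'")
  if (any(counts < 0)) stop("negative COG counts")
  structure(list(counts = counts), class = "cog_table")
}

#' Read a COG annotation table
#'
#' Two tab-separated forms are accepted: per-category counts
#' (`genome_id  category  count`) or per-protein assignments
#' (`genome_id  protein_id  category`), which are counted internally.
#'
#' @param path TSV file path.
#' @return A [cog_table].
#' @export
read_cog_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) != 3L) stop("expected 3 tab-separated columns in ", path)
  numeric3 <- grepl("^[0-9]+$", df[[3L]])
  if (all(numeric3)) {       # genome, category, count
    genome <- df[[1L]]; category <- df[[2L]]; n <- as.integer(df[[3L]])
  } else {                   # genome, protein, category
    genome <- df[[1L]]; category <- df[[3L]]; n <- rep(1L, nrow(df))
  }
  bad <- setdiff(unique(category), COG_CATEGORIES)
  if (length(bad)) stop("unknown COG category '", bad[1L], "'")
  counts <- tapply(n, list(genome, category), sum, default = 0L)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  cog_table(counts)
}

#' Write a COG table in per-category count form
#'
#' @param x a [cog_table].
#' @param path output path.
#' @export
write_cog_table <- function(x, path) {
  stopifnot(inherits(x, "cog_table"))
  long <- expand.grid(genome_id = rownames(x$counts),
                      category = colnames(x$counts),
                      stringsAsFactors = FALSE)
  long$count <- as.vector(x$counts)
  long <- long[long$count > 0L, ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome group-label configuration
#'
#' YAML mapping `genome_id -> {group, pressure_opt, fasta}`; `pressure_opt`
#' (MPa) and `fasta` are optional.
#'
#' @param path YAML file path.
#' @return data.frame with columns genome_id, group, pressure_opt, fasta.
#' @export
read_group_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0L) stop("empty group config ", path)
  df <- data.frame(
    genome_id = names(cfg),
    group = vapply(cfg, function(x) match.arg(x$group, GROUP_LEVELS),
                   character(1L)),
    pressure_opt = vapply(cfg, function(x)
      if (is.null(x$pressure_opt)) NA_real_ else as.numeric(x$pressure_opt),
      numeric(1L)),
    fasta = vapply(cfg, function(x)
      if (is.null(x$fasta)) NA_character_ else x$fasta, character(1L)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Write a genome group-label configuration
#'
#' @param df data.frame as returned by [read_group_config()].
#' @param path output YAML path.
#' @export
write_group_config <- function(df, path) {
  cfg <- lapply(seq_len(nrow(df)), function(i) {
    x <- list(group = df$group[i])
    if (!is.na(df$pressure_opt[i])) x$pressure_opt <- df$pressure_opt[i]
    if (!is.null(df$fasta) && !is.na(df$fasta[i])) x$fasta <- df$fasta[i]
    x
  })
  names(cfg) <- df$genome_id
  yaml::write_yaml(cfg, path)
  invisible(path)
}
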