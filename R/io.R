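# All tables are tab-separated UTF-8, '.' decimal, no quoting; lines starting
# with '#' before the header are treated as comments.

read_tsv_ <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv_ <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an allele-count table
#'
#' Expects header columns `snp_id`, `chrom`, `pos`, `panel`, then paired
#' columns `<pop>.k` and `<pop>.n` for every population.
#'
#' @param path file path.
#' @param panel optional [population_panel()]; populations are then matched by
#'   name and reordered to panel order.
#' @return An [allele_counts()] object; row order is preserved.
#' @export
read_allele_counts <- function(path, panel = NULL) {
  df <- read_tsv_(path)
  need <- c("snp_id", "chrom", "pos", "panel")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_ecoscan("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  rest <- setdiff(names(df), need)
  kcols <- grep("\\.k$", rest, value = TRUE)
  pops <- sub("\\.k$", "", kcols)
  ncols <- paste0(pops, ".n")
  miss <- setdiff(ncols, rest)
  if (length(miss))
    stop_ecoscan("%s: missing paired count column(s) %s", path, paste(miss, collapse = ", "))
  k <- as.matrix(df[kcols]); colnames(k) <- pops
  n <- as.matrix(df[ncols]); colnames(n) <- pops
  out <- allele_counts(df[need], k, n)
  if (!is.null(panel)) out <- align_populations(out, panel$population)
  out
}

#' Write an allele-count table
#'
#' @param counts an [allele_counts()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  km <- counts$k; nm <- counts$n
  colnames(km) <- paste0(counts$populations, ".k")
  colnames(nm) <- paste0(counts$populations, ".n")
  ord <- as.vector(rbind(colnames(km), colnames(nm)))
  write_tsv_(cbind(counts$snps, as.data.frame(cbind(km, nm))[ord]), path)
}

#' Read an environment table
#'
#' One row per population, one column per environmental variable (native
#' units; standardization happens at scan time).
#'
#' @param path file path (`population` column plus numeric variable columns).
#' @param panel optional [population_panel()]; every panel population must be
#'   present, and rows are reordered to panel order.
#' @return Data frame of class `environment_table`.
#' @export
read_environment <- function(path, panel = NULL) {
  df <- read_tsv_(path)
  if (!"population" %in% names(df)) stop_ecoscan("%s: missing 'population' column", path)
  if (anyDuplicated(df$population))
    stop_ecoscan("%s: duplicate population rows", path)
  vars <- setdiff(names(df), "population")
  for (v in vars) {
    if (!is.numeric(df[[v]]) || any(!is.finite(df[[v]])))
      stop_ecoscan("%s: variable '%s' has non-finite or non-numeric values", path, v)
  }
  if (!is.null(panel)) {
    miss <- setdiff(panel$population, df$population)
    if (length(miss))
      stop_ecoscan("%s: missing environment rows for population(s): %s",
                   path, paste(miss, collapse = ", "))
    df <- df[match(panel$population, df$population), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("environment_table", "data.frame")
  df
}

#' @rdname read_environment
#' @param env an `environment_table`.
#' @export
write_environment <- function(env, path) write_tsv_(env, path)

#' Read a SNP annotation table
#'
#' @param path TSV with columns `snp_id`, `class`
#'   (one of `nonsynonymous`, `genic`, `nongenic`) and `gene_id` (empty for
#'   nongenic SNPs).
#' @param counts optional [allele_counts()]; annotated SNPs absent from it are
#'   an error unless `permissive = TRUE`, in which case they are dropped with
#'   a warning.
#' @param permissive drop unknown SNPs instead of failing.
#' @return Data frame of class `annotation_table`.
#' @export
read_annotations <- function(path, counts = NULL, permissive = FALSE) {
  df <- read_tsv_(path)
  miss <- setdiff(c("snp_id", "class", "gene_id"), names(df))
  if (length(miss)) stop_ecoscan("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  df$gene_id[is.na(df$gene_id)] <- ""
  bad <- setdiff(unique(df$class), c("nonsynonymous", "genic", "nongenic"))
  if (length(bad))
    stop_ecoscan("%s: unknown functional class(es): %s", path, paste(bad, collapse = ", "))
  if (any(df$class == "nonsynonymous" & df$gene_id == ""))
    stop_ecoscan("%s: nonsynonymous SNPs must carry a gene_id", path)
  if (!is.null(counts)) {
    unknown <- setdiff(df$snp_id, counts$snps$snp_id)
    if (length(unknown)) {
      if (!permissive)
        stop_ecoscan("%s: %d annotated SNP(s) absent from the count matrix (e.g. %s)",
                     path, length(unknown), paste(utils::head(unknown, 3), collapse = ", "))
      warning(sprintf("dropping %d annotated SNP(s) absent from the count matrix",
                      length(unknown)))
      df <- df[!df$snp_id %in% unknown, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' @rdname read_annotations
#' @param annotations an `annotation_table`.
#' @export
write_annotations <- function(annotations, path) write_tsv_(annotations, path)

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' one or more gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (class `gene_set_collection`) with
#'   a `description` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_ecoscan("%s: malformed GMT line %d (fewer than 3 tab-separated fields)",
                 path, short[1])
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) stop_ecoscan("%s: duplicate gene-set names", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, "", 2L), nms)
  class(sets) <- "gene_set_collection"
  sets
}

#' @rdname read_gene_sets
#' @param sets a `gene_set_collection` (or plain named list of gene ids).
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description") %||% stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a GWAS catalog extract
#'
#' @param path TSV with columns `snp_id`, `trait`, `p_value`; p-values must
#'   lie in (0, 1] and (snp, trait) pairs must be unique.
#' @return Data frame of class `gwas_catalog`.
#' @export
read_gwas_catalog <- function(path) {
  df <- read_tsv_(path)
  miss <- setdiff(c("snp_id", "trait", "p_value"), names(df))
  if (length(miss)) stop_ecoscan("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$p_value) | df$p_value <= 0 | df$p_value > 1)
  if (length(bad))
    stop_ecoscan("%s: p_value outside (0,1] at row %d (snp '%s')",
                 path, bad[1], df$snp_id[bad[1]])
  if (anyDuplicated(df[c("snp_id", "trait")]))
    stop_ecoscan("%s: duplicate (snp_id, trait) pairs", path)
  class(df) <- c("gwas_catalog", "data.frame")
  df
}

#' @rdname read_gwas_catalog
#' @param catalog a `gwas_catalog`.
#' @export
write_gwas_catalog <- function(catalog, path) write_tsv_(catalog, path)

#' Write and re-read scan results
#'
#' The table holds one row per SNP with its panel, pooled derived-allele
#' frequency, exclusion flag and one `log10 BF` column per variable, written
#' at 4 decimals; the population set and prior scale are stored in comment
#' lines so that a round trip reconstructs the object to written precision.
#'
#' @param scan a `scan_result` from [climate_scan()].
#' @param path output path.
#' @return `path` invisibly (`write_scan_results`); a `scan_result`
#'   (`read_scan_results`).
#' @export
write_scan_results <- function(scan, path) {
  bf <- scan$bf
  df <- data.frame(scan$snps, stringsAsFactors = FALSE)
  for (v in scan$variables) {
    col <- sprintf("%.4f", bf[, v])
    col[is.na(bf[, v])] <- "NA"
    df[[paste0("log10bf.", v)]] <- col
  }
  write_tsv_(df, path, comments = c(
    paste0("population_set=", scan$population_set),
    paste0("tau=", format(scan$tau, digits = 15)),
    paste0("variables=", paste(scan$variables, collapse = ","))))
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  header <- readLines(path, n = 20L)
  header <- header[startsWith(header, "# ")]
  meta <- sub("^# ", "", header)
  get_meta <- function(key) {
    hit <- meta[startsWith(meta, paste0(key, "="))]
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, "="), "", hit[1])
  }
  df <- read_tsv_(path)
  vars <- strsplit(get_meta("variables") %||% "", ",")[[1]]
  bf <- as.matrix(df[paste0("log10bf.", vars)])
  colnames(bf) <- vars
  rownames(bf) <- df$snp_id
  snp_cols <- setdiff(names(df), paste0("log10bf.", vars))
  structure(list(snps = df[snp_cols], bf = bf, variables = vars,
                 population_set = get_meta("population_set") %||% "worldwide",
                 tau = as.numeric(get_meta("tau") %||% "1")),
            class = "scan_result")
}

#' Write an enrichment report
#'
#' @param report an `enrichment_report` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(report, path) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is_whole_col, TRUE)
  for (col in names(df)[num]) df[[col]] <- sprintf("%.6f", df[[col]])
  write_tsv_(df, path)
}

is_whole_col <- function(x) is.numeric(x) && all(is_whole(x) | is.na(x))

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; '#' starts a comment. Values are parsed
#' as numbers, logicals or comma-separated vectors where possible.
#'
#' @param path file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop_ecoscan("config line without '=': '%s'", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) {
      out[[key]] <- num
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      out[[key]] <- tolower(parts) == "true"
    } else {
      out[[key]] <- if (length(parts) == 1L) val else parts
    }
  }
  out
}

#' Write a simulated dataset to a directory
#'
#' Writes the five analysis inputs (allele counts, environment table,
#' annotations, gene sets, GWAS-style truth extract) plus the ground-truth
#' labels of the generator.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_allele_counts(sim$counts, file.path(dir, "allele_counts.tsv"))
  write_environment(sim$env, file.path(dir, "environment.tsv"))
  write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  write_gene_sets(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_tsv_(sim$truth, file.path(dir, "truth.tsv"))
  panel <- sim$panel
  write_tsv_(as.data.frame(panel), file.path(dir, "populations.tsv"))
  invisible(dir)
}
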