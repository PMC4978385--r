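#' Read a GenePop file
#'
#' Parses the GenePop exchange dialect: a title line, locus names (one per
#' line or comma-separated), `Pop` separators, and per-individual rows of
#' 2- or 3-digit diploid genotypes. Both `id , g g g` and whitespace-only
#' rows are accepted. `00`/`000` alleles map to missing; the digit width is
#' auto-detected and recorded in the `digits` attribute.
#'
#' @param path file path
#' @param pop_labels optional character vector of population labels, one per
#'   `Pop` block; defaults to `"1"`, `"2"`, ... in file order.
#' @return a [genotype_dataset()] (stage `"unknown"` throughout; stages live
#'   in a sidecar CSV, see [read_stage_csv()])
#' @export
read_genepop <- function(path, pop_labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (length(lines) < 3L) stop("GenePop file too short: ", path)
  body <- lines[-1L]                      # drop title
  is_pop <- toupper(body) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found in ", path)
  locus_lines <- body[seq_len(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names before first 'Pop' in ", path)
  L <- length(loci)

  blocks <- cumsum(is_pop)
  rows <- which(!is_pop & blocks > 0L & nzchar(body))
  if (!length(rows)) stop("empty Pop block in ", path)
  nblk <- max(blocks)
  if (any(tabulate(blocks[rows], nblk) == 0L))
    stop("empty Pop block in ", path)
  if (is.null(pop_labels)) pop_labels <- as.character(seq_len(nblk))
  if (length(pop_labels) != nblk)
    stop("pop_labels must have one entry per Pop block (", nblk, ")")

  ids <- character(length(rows))
  pop <- pop_labels[blocks[rows]]
  geno <- vector("list", length(rows))
  digits <- NA_integer_
  for (i in seq_along(rows)) {
    line <- body[rows[i]]
    if (grepl(",", line, fixed = TRUE)) {
      parts <- strsplit(line, ",", fixed = TRUE)[[1]]
      ids[i] <- trimws(parts[1])
      gtoks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
    } else {
      toks <- strsplit(line, "[ \t]+")[[1]]
      ids[i] <- toks[1]
      gtoks <- toks[-1]
    }
    gtoks <- gtoks[nzchar(gtoks)]
    if (length(gtoks) != L)
      stop(sprintf("line %d of %s: expected %d genotypes, found %d",
                   rows[i] + 1L, path, L, length(gtoks)))
    w <- unique(nchar(gtoks))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop(sprintf("line %d of %s: genotype tokens must be 4 or 6 digits",
                   rows[i] + 1L, path))
    w <- w / 2L
    if (is.na(digits)) digits <- w
    else if (digits != w)
      stop(sprintf("line %d of %s: inconsistent allele digit width",
                   rows[i] + 1L, path))
    a1 <- as.integer(substr(gtoks, 1L, w))
    a2 <- as.integer(substr(gtoks, w + 1L, 2L * w))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    geno[[i]] <- as.integer(rbind(a1, a2))
  }
  alleles <- matrix(unlist(geno), nrow = length(rows), byrow = TRUE)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  # when ids look like "<site>_<rest>" with one shared prefix per block and
  # distinct prefixes across blocks, adopt the prefixes as labels
  if (is.null(match.call()$pop_labels) && all(grepl("_", ids))) {
    pre <- sub("_.*$", "", ids)
    per_block <- tapply(pre, blocks[rows], unique)
    if (all(lengths(per_block) == 1L) &&
        !anyDuplicated(unlist(per_block)))
      pop <- unlist(per_block)[blocks[rows]]
  }
  ds <- genotype_dataset(alleles, loci, ids, pop)
  attr(ds, "digits") <- digits
  ds
}

#' Write a GenePop file
#'
#' Emits the comma-separated GenePop form, choosing 2-digit encoding when all
#' allele sizes fit in two digits and 3-digit otherwise.
#'
#' @param ds a [genotype_dataset()]
#' @param path output file path
#' @param title title line (first line of the file)
#' @return `path`, invisibly
#' @export
write_genepop <- function(ds, path, title = "popland genotypes") {
  tab <- table(ds$pop)
  if (any(tab == 0L) || !length(ds$individuals))
    stop("refusing to write an empty population")
  mx <- suppressWarnings(max(ds$alleles, na.rm = TRUE))
  if (!is.finite(mx)) mx <- 1L
  digits <- if (mx <= 99L) 2L else if (mx <= 999L) 3L else
    stop("allele size ", mx, " exceeds 3-digit GenePop encoding")
  fmt <- paste0("%0", digits, "d")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(ds$loci, con)
  for (p in pop_names(ds)) {
    writeLines("Pop", con)
    for (i in which(ds$pop == p)) {
      a <- ds$alleles[i, ]
      a[is.na(a)] <- 0L
      g <- paste0(sprintf(fmt, a[c(TRUE, FALSE)]), sprintf(fmt, a[c(FALSE, TRUE)]))
      writeLines(paste0(ds$individuals[i], " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read an individual life-stage sidecar CSV
#'
#' @param path CSV with header `individual,stage`
#' @param ds optional [genotype_dataset()] whose stages to fill in
#' @return if `ds` given, the dataset with stages set; else the data frame
#' @export
read_stage_csv <- function(path, ds = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "stage") %in% names(df)))
  if (is.null(ds)) return(df)
  m <- match(ds$individuals, df$individual)
  st <- ifelse(is.na(m), "unknown", df$stage[m])
  genotype_dataset(ds$alleles, ds$loci, ds$individuals, ds$pop, st)
}

#' Read a site-coordinate sidecar CSV
#'
#' @param path CSV with header `site,x,y` (projected meters)
#' @return data frame with character `site` and numeric `x`, `y`
#' @export
read_sites_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site", "x", "y") %in% names(df)))
  df$site <- as.character(df$site)
  df
}

#' Write a site-coordinate sidecar CSV
#' @param sites data frame with `site`, `x`, `y`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sites_csv <- function(sites, path) {
  write.csv(sites[, c("site", "x", "y")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
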