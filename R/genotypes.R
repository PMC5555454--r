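#' Validate a genotype matrix
#'
#' A genotype matrix is an integer matrix of ALT-allele dosages with
#' accessions in rows and markers in columns. Entries are 0, 1, 2 or `NA`
#' (missing call). Row and column names carry the accession and marker ids
#' and must be unique.
#'
#' All downstream statistics (MAF, He, r2, F_ST, Jost's D) are invariant
#' under the allele-orientation flip `g -> 2 - g`, so which allele is
#' designated ALT is arbitrary.
#'
#' @param G matrix to validate.
#' @return `G`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_genotypes <- function(G) {
  if (!is.matrix(G)) stop("genotype matrix must be a matrix")
  if (is.null(rownames(G)) || is.null(colnames(G)))
    stop("genotype matrix must have accession rownames and marker colnames")
  if (anyDuplicated(rownames(G)))
    stop("duplicate accession ids: ",
         paste(unique(rownames(G)[duplicated(rownames(G))]), collapse = ", "))
  if (anyDuplicated(colnames(G)))
    stop("duplicate marker ids: ",
         paste(unique(colnames(G)[duplicated(colnames(G))]), collapse = ", "))
  vals <- G[!is.na(G)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  invisible(G)
}

#' Read a genotype matrix from a delimited table or a VCF
#'
#' Table layout: first column = accession id, header row = marker ids,
#' cells in \{0, 1, 2, NA\} (`-9` also accepted as missing). The delimiter
#' is sniffed (tab vs comma) unless given. VCF input must be v4.x; only
#' biallelic SNP records are used and the GT field is converted to the
#' ALT-allele dosage (`./.` and `.` become missing).
#'
#' @param path file path.
#' @param format `"table"` or `"vcf"`.
#' @param delim optional field delimiter for tables (`"\t"` or `","`).
#' @param multiallelic for VCF input, `"skip"` (drop multi-allelic records,
#'   default) or `"error"`.
#' @return a validated genotype matrix (accessions x markers).
#' @export
read_genotypes <- function(path, format = c("table", "vcf"), delim = NULL,
                           multiallelic = c("skip", "error")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(read_genotypes_vcf(path, match.arg(multiallelic)))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(tab) < 2L) stop("genotype table needs an accession column and at least one marker")
  acc <- tab[[1L]]
  markers <- colnames(tab)[-1L]
  if (anyDuplicated(acc)) stop("duplicate accession ids in genotype table")
  if (anyDuplicated(markers)) stop("duplicate marker column ids in genotype table")
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  cells[cells %in% c("NA", "", "-9", ".")] <- NA_character_
  bad <- which(!is.na(cells) & !cells %in% c("0", "1", "2"), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed genotype '%s' at accession '%s', marker '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]], acc[bad[1L, 1L]],
                 markers[bad[1L, 2L]]))
  }
  G <- matrix(as.integer(cells), nrow = length(acc),
              dimnames = list(acc, markers))
  validate_genotypes(G)
  G
}

read_genotypes_vcf <- function(path, multiallelic = "skip") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (!all(bi)) {
    if (multiallelic == "error") stop("multi-allelic records in VCF: ", path)
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- unname(rownames(gt))
  fix <- vcfR::getFIX(vcf)
  noid <- is.na(ids) | ids == "."
  if (any(noid)) ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  ids <- as.vector(ids)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = list(ids, colnames(gt)))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0", "0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1", "1")] <- 2L
  G <- t(dos)
  validate_genotypes(G)
  G
}

#' Write a genotype matrix as a tab-separated table
#'
#' Inverse of [read_genotypes()] for table input: first column `accession`,
#' one column per marker, missing as `NA`.
#'
#' @param G genotype matrix.
#' @param path output path.
#' @export
write_genotypes <- function(G, path) {
  validate_genotypes(G)
  out <- data.frame(accession = rownames(G), G, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF v4.2 with one biallelic record per marker (REF=A, ALT=C as
#' placeholder alleles) and unphased GT calls. When a marker map is given,
#' CHROM/POS come from the scaffold and bp columns where present, else from
#' the linkage group with the marker index as position.
#'
#' @param G genotype matrix.
#' @param path output path.
#' @param map optional marker map (see [read_map()]).
#' @export
write_vcf <- function(G, path, map = NULL) {
  validate_genotypes(G)
  m <- ncol(G)
  chrom <- rep("0", m); pos <- seq_len(m)
  if (!is.null(map)) {
    idx <- match(colnames(G), map$marker)
    hit <- !is.na(idx)
    if ("scaffold" %in% names(map)) {
      sc <- map$scaffold[idx[hit]]
      bp <- map$bp[idx[hit]]
      use <- !is.na(sc)
      chrom[hit][use] <- sc[use]
      pos[hit][use] <- bp[use]
      chrom[hit][!use] <- as.character(map$linkage_group[idx[hit]][!use])
    } else {
      chrom[hit] <- as.character(map$linkage_group[idx[hit]])
    }
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    calls <- ifelse(is.na(G[, j]), "./.", gt_code[as.character(G[, j])])
    paste(c(chrom[j], pos[j], colnames(G)[j], "A", "C", ".", "PASS", ".",
            "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a marker map
#'
#' Expected columns: `marker`, `linkage_group`, `cM` and optionally
#' `scaffold` + `bp` (1-based physical coordinates, present together or not
#' at all). Column names can be remapped for files using a different
#' layout via `col_map`, e.g. `c(marker = "SNP", cM = "position")`.
#'
#' @param path tab-separated file with a header.
#' @param col_map optional named character vector mapping the canonical
#'   names to the file's column names.
#' @return data.frame with columns `marker`, `linkage_group`, `cM` and,
#'   when available, `scaffold`, `bp`.
#' @export
read_map <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(tab))
      if (is.na(j)) stop("column '", col_map[[canon]], "' not found in map")
      names(tab)[j] <- canon
    }
  }
  need <- c("marker", "linkage_group", "cM")
  if (!all(need %in% names(tab)))
    stop("map must have columns: ", paste(need, collapse = ", "))
  map <- tab[, intersect(c(need, "scaffold", "bp"), names(tab)), drop = FALSE]
  validate_map(map)
  map
}

#' @rdname read_map
#' @param map marker map data.frame to validate.
#' @export
validate_map <- function(map) {
  if (anyDuplicated(map$marker))
    stop("duplicate markers in map: ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  if (any(is.na(map$cM)) || any(map$cM < 0))
    stop("cM positions must be non-negative")
  has_sc <- "scaffold" %in% names(map)
  has_bp <- "bp" %in% names(map)
  if (has_sc != has_bp)
    stop("scaffold and bp columns must be present together")
  if (has_sc && any(!is.na(map$scaffold) != !is.na(map$bp)))
    stop("bp must be present exactly where scaffold is present")
  if (has_bp && any(map$bp[!is.na(map$bp)] < 0))
    stop("bp positions must be non-negative")
  invisible(map)
}

#' Read a group assignment table
#'
#' Two-column tab-separated file `accession<TAB>group`. When a genotype
#' matrix is supplied every assigned accession must exist in it.
#'
#' @param path file path.
#' @param G optional genotype matrix to validate against.
#' @return data.frame with columns `accession`, `group`.
#' @export
read_groups <- function(path, G = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("accession", "group") %in% names(tab)))
    stop("groups file must have columns 'accession' and 'group'")
  groups <- tab[, c("accession", "group")]
  if (!is.null(G)) validate_groups(groups, G)
  groups
}

#' @rdname read_groups
#' @param groups group assignment data.frame.
#' @export
validate_groups <- function(groups, G) {
  missing_acc <- setdiff(groups$accession, rownames(G))
  if (length(missing_acc))
    stop("accessions in group table absent from genotypes: ",
         paste(utils::head(missing_acc, 5), collapse = ", "))
  invisible(groups)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; numeric (double) columns are written at
#' fixed 6-decimal precision.
#'
#' @param records non-empty data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      out[[j]] <- ifelse(is.na(v), "NA", sprintf("%.6f", v))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_groups
#' @export
write_groups <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_map
#' @param path output path.
#' @export
write_map <- function(map, path) {
  validate_map(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square pairwise matrix (distance / IBS / kinship) as TSV
#'
#' @param M square matrix with accession dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(M, path) {
  out <- data.frame(accession = rownames(M), M, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
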