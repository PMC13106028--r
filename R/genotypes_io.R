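#' Construct a genotype block
#'
#' The container for biallelic genotype dosages: a variant table, an
#' ordered participant vector and an n-participants by n-variants dosage
#' matrix in {0, 1, 2, NA}. Allele statistics (AAF, MAC) are filled by
#' \code{\link{compute_allele_stats}}.
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} and canonical \code{id}
#'   (\code{chrom:pos:ref:alt}).
#' @param participants character vector of participant ids.
#' @param dosage integer matrix, rows = participants, cols = variants.
#' @return object of class \code{genotype_block}.
#' @export
genotype_block <- function(variants, participants, dosage) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(dosage) == length(participants),
            ncol(dosage) == nrow(variants))
  if (any(variants$ref == variants$alt))
    stop("genotype_block: ref and alt alleles must differ")
  if (any(variants$pos < 1))
    stop("genotype_block: positions are 1-based")
  if (!"id" %in% names(variants))
    variants$id <- paste(variants$chrom, variants$pos, variants$ref,
                         variants$alt, sep = ":")
  structure(list(variants = variants, participants = participants,
                 dosage = dosage), class = "genotype_block")
}

#' @export
print.genotype_block <- function(x, ...) {
  cat("genotype_block:", length(x$participants), "participants x",
      nrow(x$variants), "variants\n")
  if ("aaf" %in% names(x$variants))
    cat("  AAF range:", signif(range(x$variants$aaf, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Compute per-variant allele statistics
#'
#' Fills the variant table with \code{n_nonmissing}, \code{aaf}
#' (alternate-allele fraction, missing dosages excluded from the
#' denominator) and \code{mac} (minor-allele count, the smaller of the
#' alt and ref allele counts). Variants with all dosages missing get
#' \code{aaf = NA} and are flagged in \code{all_missing}.
#'
#' @param block a \code{genotype_block}.
#' @return the block with statistics filled.
#' @export
compute_allele_stats <- function(block) {
  stopifnot(inherits(block, "genotype_block"))
  d <- block$dosage
  n_nm <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  aaf <- ifelse(n_nm > 0, alt / (2 * n_nm), NA_real_)
  mac <- pmin(alt, 2 * n_nm - alt)
  block$variants$n_nonmissing <- n_nm
  block$variants$aaf <- aaf
  block$variants$mac <- mac
  block$variants$all_missing <- n_nm == 0
  block
}

#' Filter variants by minor-allele count
#'
#' Retains exactly the variants with MAC strictly greater than
#' \code{mac_min} ("greater than", so a variant at exactly the threshold
#' is removed). Applied per analysis cohort, never globally.
#'
#' @param block a \code{genotype_block} with statistics computed.
#' @param mac_min minor-allele-count threshold (20 for visit-based
#'   cohorts, 40 for the EHR cohort in the default pipeline).
#' @return the filtered \code{genotype_block}.
#' @export
filter_by_mac <- function(block, mac_min) {
  stopifnot(inherits(block, "genotype_block"),
            "mac" %in% names(block$variants))
  keep <- !is.na(block$variants$mac) & block$variants$mac > mac_min
  block$variants <- block$variants[keep, , drop = FALSE]
  block$dosage <- block$dosage[, keep, drop = FALSE]
  block
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (GT field required) into a
#' \code{genotype_block}. Dosage is the alt-allele count of the genotype
#' call; missing genotypes (\code{./.}) become NA. Multiallelic records
#' are split into biallelic variants that share a position tag
#' (\code{multi_pos}) consumed by the meta-analysis multivalent-removal
#' rule.
#'
#' @param path VCF file path.
#' @return a \code{genotype_block} with allele statistics computed.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  participants <- colnames(gt)

  var_rows <- list()
  dos_cols <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    g <- gt[i, ]
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    for (a in seq_along(alts)) {
      dos <- vapply(alleles, function(x) {
        if (length(x) == 0 || any(x == ".") || any(is.na(x)))
          return(NA_integer_)
        sum(x == as.character(a))
      }, integer(1))
      var_rows[[length(var_rows) + 1]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        multi_pos = length(alts) > 1, stringsAsFactors = FALSE)
      dos_cols[[length(dos_cols) + 1]] <- dos
    }
  }
  variants <- do.call(rbind, var_rows)
  variants$id <- paste(variants$chrom, variants$pos, variants$ref,
                       variants$alt, sep = ":")
  dosage <- do.call(cbind, dos_cols)
  colnames(dosage) <- variants$id
  rownames(dosage) <- participants
  compute_allele_stats(genotype_block(variants, participants, dosage))
}

#' Write a genotype block as VCF 4.2
#'
#' Emits a minimal plain-text VCF with a GT FORMAT field; dosages 0/1/2
#' become 0/0, 0/1, 1/1 and NA becomes \code{./.}.
#'
#' @param block a \code{genotype_block}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_vcf <- function(block, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=copdwl",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", block$participants), collapse = "\t"))
  v <- block$variants
  lines <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    d <- block$dosage[, i]
    g <- ifelse(is.na(d), "./.", gt_codes[d + 1])
    lines[i] <- paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i],
                        v$alt[i], ".", "PASS", ".", "GT", g),
                      collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a gene group file
#'
#' One gene per line: gene symbol followed by whitespace-separated member
#' variant ids. Duplicate gene symbols are an error naming the offending
#' line.
#'
#' @param path group file path.
#' @param block optional \code{genotype_block}; when supplied, member ids
#'   not present in the block are counted per gene in \code{n_unmatched}
#'   with a warning.
#' @return data.frame (gene, variant_id), one row per membership, with a
#'   per-gene \code{attr(, "unmatched")} table when \code{block} given.
#' @export
read_group_file <- function(path, block = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(gene = character(0), variant_id = character(0)))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  genes <- vapply(parts, `[`, character(1), 1)
  dup <- duplicated(genes)
  if (any(dup))
    stop(sprintf("read_group_file: duplicate gene '%s' at line %d",
                 genes[which(dup)[1]], which(dup)[1]))
  out <- do.call(rbind, lapply(parts, function(p) {
    if (length(p) < 2) return(NULL)
    data.frame(gene = p[1], variant_id = p[-1], stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(gene = character(0), variant_id = character(0))
  if (!is.null(block)) {
    unmatched <- !(out$variant_id %in% block$variants$id)
    if (any(unmatched))
      warning(sprintf("read_group_file: %d member ids unmatched in block",
                      sum(unmatched)))
    attr(out, "unmatched") <- tapply(unmatched, out$gene, sum)
  }
  out
}

#' Write a gene group file
#' @param masks data.frame (gene, variant_id).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_group_file <- function(masks, path) {
  genes <- unique(masks$gene)
  lines <- vapply(genes, function(g) {
    paste(c(g, masks$variant_id[masks$gene == g]), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format weights table
#' @param path TSV with header participant_id, time_days, weight_kg, bmi.
#' @return data.frame.
#' @export
read_weights <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a covariates table
#' @param path TSV with header participant_id, age, sex, pc1..pc5,
#'   pack_years, fev1_fvc, icd_codes, cohort.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
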