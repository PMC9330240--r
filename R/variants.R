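#' Define a candidate variant
#'
#' A registry entry for one biallelic SNP in the candidate panel: its dbSNP
#' identifier, gene, cytogenetic band, major/minor alleles and the direction
#' of effect on therapy response reported in the pharmacogenetic literature
#' (relative to the minor allele).
#'
#' @param dbsnp_id dbSNP identifier, `"rs"` followed by digits.
#' @param gene Gene symbol.
#' @param region Cytogenetic band, e.g. `"6q25.3"`.
#' @param major_allele,minor_allele Single-character nucleotides; must differ.
#' @param reported_direction One of `"increased"`, `"decreased"`, `"mixed"`,
#'   `"side_effects"`.
#' @param maf Default minor allele frequency used by the cohort simulator.
#'
#' @return A one-row data frame of class `variant_spec`.
#' @export
variant_spec <- function(dbsnp_id, gene, region, major_allele, minor_allele,
                         reported_direction = c("increased", "decreased",
                                                "mixed", "side_effects"),
                         maf = NA_real_) {
  stopifnot(is.character(dbsnp_id), length(dbsnp_id) == 1L)
  if (!grepl("^rs[0-9]+$", dbsnp_id))
    stop("dbsnp_id must match 'rs' + digits, got: ", dbsnp_id)
  reported_direction <- match.arg(reported_direction)
  if (!nchar(major_allele) == 1L || !nchar(minor_allele) == 1L)
    stop("alleles must be single characters")
  if (identical(major_allele, minor_allele))
    stop("major and minor allele must differ")
  if (!is.na(maf) && (maf < 0 || maf > 1))
    stop("maf must lie in [0, 1]")
  out <- data.frame(
    dbsnp_id = dbsnp_id, gene = gene, region = region,
    major_allele = major_allele, minor_allele = minor_allele,
    reported_direction = reported_direction, maf = maf,
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_spec", class(out))
  out
}

#' The default five-variant candidate panel
#'
#' Metformin-response candidate SNPs in the ATM, SLC22A1, SLC47A1 and SLC2A2
#' genes (transporter and signalling loci recurrently implicated in glycemic
#' response). Default minor allele frequencies are the pooled allele
#' frequencies across all metformin-treated responders and non-responders in
#' the study cohort the simulator emulates.
#'
#' @return A data frame with one row per variant (class `variant_spec`).
#' @export
default_variants <- function() {
  rbind(
    variant_spec("rs11212617", "ATM",     "11q22.3", "A", "C", "increased",
                 maf = 286 / 598),
    variant_spec("rs628031",   "SLC22A1", "6q25.3",  "G", "A", "side_effects",
                 maf = 222 / 596),
    variant_spec("rs12208357", "SLC22A1", "6q25.3",  "C", "T", "decreased",
                 maf = 51 / 594),
    variant_spec("rs2289669",  "SLC47A1", "17p11.2", "G", "A", "mixed",
                 maf = 194 / 598),
    variant_spec("rs8192675",  "SLC2A2",  "3q26.2",  "A", "G", "increased",
                 maf = 151 / 596)
  )
}

#' Genotype class labels for a variant
#'
#' Maps minor-allele counts 0, 1, 2 to two-letter genotype labels
#' (homozygous major, heterozygote with alleles in alphabetical order,
#' homozygous minor).
#'
#' @param variant One row of a `variant_spec` data frame.
#' @return Character vector of length 3, named `"0"`, `"1"`, `"2"`.
#' @export
genotype_classes <- function(variant) {
  het <- paste(sort(c(variant$major_allele, variant$minor_allele)),
               collapse = "")
  out <- c(strrep(variant$major_allele, 2), het,
           strrep(variant$minor_allele, 2))
  names(out) <- c("0", "1", "2")
  out
}
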