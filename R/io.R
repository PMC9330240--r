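# Cohort file dialect: UTF-8 TSV, header required, empty field = missing.
# Genotypes are stored as minor-allele counts; two-letter genotype strings
# (e.g. "CT", order-insensitive) are also accepted on read and resolved
# against the variant registry's alleles.

cohort_required_columns <- function() {
  c("subject_id", "sex", "age", "bmi", "whr", "creatinine", "fbg",
    "hba1c", "family_history", "therapy", "response")
}

#' Write a cohort table to TSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$family_history <- as.integer(out$family_history)
  for (col in names(out)) {
    # %.17g keeps doubles bit-exact through the text round trip
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Reads the TSV dialect written by [write_cohort()]: required phenotype,
#' therapy and response columns plus one genotype column per registry
#' variant (minor-allele counts 0/1/2, two-letter genotype strings, or empty
#' for missing). Schema violations name the offending column; value-level
#' violations report the row numbers.
#'
#' @param path Path to the TSV file.
#' @param variants Variant registry used to validate genotype columns and
#'   resolve two-letter genotypes.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path, variants = default_variants()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = "",
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_required_columns(), names(raw))
  if (length(missing_cols))
    config_error("cohort file lacks required column(s): ",
                 paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw),
                   c(cohort_required_columns(), variants$dbsnp_id))
  if (length(extra))
    warning("ignoring extraneous column(s): ", paste(extra, collapse = ", "))
  out <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  parse_cat <- function(col, allowed) {
    v <- raw[[col]]
    bad <- which(!is.na(v) & !v %in% allowed)
    if (length(bad))
      stop("column '", col, "': invalid value(s) at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    v
  }
  out$sex <- parse_cat("sex", c("male", "female"))
  for (col in c("age", "bmi", "whr", "creatinine", "fbg", "hba1c")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad))
      stop("column '", col, "': unparseable number at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    out[[col]] <- v
  }
  fh <- raw$family_history
  bad <- which(!is.na(fh) & !fh %in% c("0", "1", "TRUE", "FALSE"))
  if (length(bad))
    stop("column 'family_history': invalid value at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  out$family_history <- fh %in% c("1", "TRUE")
  out$family_history[is.na(fh)] <- NA
  out$therapy <- parse_cat("therapy", c("monotherapy", "combination"))
  out$response <- parse_cat("response", c("responder", "non_responder"))
  for (i in seq_len(nrow(variants))) {
    vid <- variants$dbsnp_id[i]
    if (!vid %in% names(raw)) next
    v <- raw[[vid]]
    g <- rep(NA_integer_, length(v))
    numeric_ok <- !is.na(v) & v %in% c("0", "1", "2")
    g[numeric_ok] <- as.integer(v[numeric_ok])
    other <- which(!is.na(v) & !numeric_ok)
    if (length(other)) {
      al <- c(variants$major_allele[i], variants$minor_allele[i])
      for (r in other) {
        chars <- strsplit(v[r], "")[[1L]]
        if (length(chars) == 2L && all(chars %in% al)) {
          g[r] <- sum(chars == variants$minor_allele[i])
        } else {
          stop("column '", vid, "': invalid genotype '", v[r],
               "' at row ", r)
        }
      }
    }
    out[[vid]] <- g
  }
  out
}

#' Ingest genotypes from a VCF file
#'
#' Extracts GT fields for the registry's rsIDs (matched on the VCF ID
#' column), converts them to minor-allele counts with the allele orientation
#' taken from the registry (the minor allele may be REF or ALT), and joins
#' them onto a cohort by subject id. Only biallelic SNVs are accepted;
#' half-calls and missing GTs become missing genotypes; a registry rsID
#' absent from the VCF yields a warning and an all-missing column.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param cohort Cohort data frame to join onto (by `subject_id`).
#' @param variants Variant registry.
#' @param sample_map Optional named character vector translating VCF sample
#'   names to cohort `subject_id`s; by default VCF sample names are used
#'   directly.
#' @return The cohort with one genotype column per registry variant.
#' @export
read_genotypes_vcf <- function(path, cohort, variants = default_variants(),
                               sample_map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  ids <- if (is.null(sample_map)) samples else {
    unname(ifelse(samples %in% names(sample_map),
                  sample_map[samples], samples))
  }
  unmatched <- setdiff(ids, cohort$subject_id)
  if (length(unmatched))
    warning("VCF sample(s) not in cohort: ",
            paste(unmatched, collapse = ", "))
  for (i in seq_len(nrow(variants))) {
    vid <- variants$dbsnp_id[i]
    row <- which(fix$ID == vid)
    if (!length(row)) {
      warning("variant ", vid, " absent from VCF; genotypes set to missing")
      cohort[[vid]] <- NA_integer_
      next
    }
    if (length(row) > 1L)
      stop("variant ", vid, " appears ", length(row), " times in VCF")
    ref <- fix$REF[row]; alt <- fix$ALT[row]
    if (grepl(",", alt, fixed = TRUE) || nchar(ref) != 1L ||
        nchar(alt) != 1L)
      stop("variant ", vid, " is not a biallelic SNV (REF=", ref,
           ", ALT=", alt, ")")
    minor <- variants$minor_allele[i]
    if (minor == alt) {
      count_allele <- "1"
    } else if (minor == ref) {
      count_allele <- "0"
    } else {
      stop("registry minor allele ", minor, " for ", vid,
           " matches neither REF nor ALT")
    }
    calls <- gt[row, ]
    counts <- vapply(calls, function(g) {
      if (is.na(g)) return(NA_integer_)
      al <- strsplit(g, "[/|]")[[1L]]
      if (length(al) != 2L || any(al == ".")) return(NA_integer_)
      sum(al == count_allele)
    }, integer(1L))
    col <- rep(NA_integer_, nrow(cohort))
    m <- match(ids, cohort$subject_id)
    ok <- !is.na(m)
    col[m[ok]] <- counts[ok]
    cohort[[vid]] <- col
  }
  cohort
}

#' Build a simulation configuration from a YAML or JSON document
#'
#' Reads a document whose fields mirror the [sim_config()] arguments
#' (`n_subjects`, `maf`, `phenotype_params` as `{trait: [mean, sd]}`,
#' `sex_fraction_male`, `family_history_prevalence`, `monotherapy_fraction`,
#' `response_model` as `{intercept:, coef: {feature: value}}`,
#' `missingness`, `seed`) and validates it through the constructor. Fields
#' not present keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [sim_config()].
#' @export
sim_config_from_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  for (f in c("n_subjects", "sex_fraction_male", "family_history_prevalence",
              "monotherapy_fraction", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$maf)) args$maf <- unlist(raw$maf)
  if (!is.null(raw$missingness)) args$missingness <- unlist(raw$missingness)
  if (!is.null(raw$phenotype_params)) {
    args$phenotype_params <- lapply(raw$phenotype_params, function(p) {
      p <- unlist(p)
      if (is.null(names(p)) || !all(c("mean", "sd") %in% names(p)))
        names(p) <- c("mean", "sd")
      p[c("mean", "sd")]
    })
  }
  if (!is.null(raw$response_model)) {
    args$response_model <- list(
      intercept = raw$response_model$intercept,
      coef = unlist(raw$response_model$coef)
    )
  }
  if (!is.null(raw$ld_haplotypes)) {
    args$ld_haplotypes <- list(
      variants = unlist(raw$ld_haplotypes$variants),
      freq = unlist(raw$ld_haplotypes$freq)
    )
  }
  do.call(sim_config, args)
}

# Internal: run manifest for reproducibility records.
run_manifest <- function(config = NULL, seeds = NULL, inputs = character(0)) {
  cfg_hash <- if (is.null(config)) NA_character_ else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    unname(tools::md5sum(tmp))
  }
  list(
    tool = "metpgx",
    version = as.character(utils::packageVersion("metpgx")),
    config_md5 = cfg_hash,
    seeds = seeds,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

# Internal: genotype/allele frequency table in the style of the four-group
# association report (counts with percentages and p1-p4 per level).
format_association_report <- function(scan) {
  lines <- character(0)
  for (v in unique(scan$variant)) {
    sub <- scan[scan$variant == v, , drop = FALSE]
    lines <- c(lines, sprintf("%s (%s)", v, sub$gene[1L]))
    for (lev in unique(sub$level)) {
      sl <- sub[sub$level == lev, , drop = FALSE]
      ps <- paste(sprintf("%s=%.4f", sl$comparison, sl$p), collapse = " ")
      r1 <- sl[1L, ]
      lines <- c(lines, sprintf(
        "  %-14s resp %4d/%-4d (%4.1f%%)  nonresp %4d/%-4d (%4.1f%%)  %s",
        lev, r1$a, r1$n_group1, 100 * r1$a / r1$n_group1,
        r1$c, r1$n_group2, 100 * r1$c / r1$n_group2, ps))
    }
  }
  lines
}

#' Write machine- and human-readable analysis reports
#'
#' Writes whatever parts are supplied: the association scan as TSV plus a
#' formatted per-variant frequency table, the resampling summary as JSON,
#' the importance profile as TSV, and a run manifest (tool version, config
#' hash, seeds, input checksums).
#'
#' @param outdir Output directory (created if absent).
#' @param association Optional [run_association_scan()] result.
#' @param replicates Optional `metpgx_replicates` result.
#' @param config Optional configuration object to hash into the manifest.
#' @param seeds Optional named list of seeds to record.
#' @param inputs Optional character vector of input paths to checksum.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(outdir, association = NULL, replicates = NULL,
                         config = NULL, seeds = NULL,
                         inputs = character(0)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  written <- character(0)
  if (!is.null(association)) {
    f <- file.path(outdir, "association_results.tsv")
    utils::write.table(association, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written["association_tsv"] <- f
    f2 <- file.path(outdir, "association_report.txt")
    writeLines(format_association_report(association), f2)
    written["association_report"] <- f2
  }
  if (!is.null(replicates)) {
    f <- file.path(outdir, "replicates.tsv")
    utils::write.table(replicates$replicates, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written["replicates_tsv"] <- f
    f2 <- file.path(outdir, "model_summary.json")
    jsonlite::write_json(replicates$summary, f2, auto_unbox = TRUE,
                         digits = NA)
    written["summary_json"] <- f2
    if (!is.null(replicates$importance)) {
      f3 <- file.path(outdir, "importance.tsv")
      utils::write.table(replicates$importance, f3, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      written["importance_tsv"] <- f3
    }
  }
  fm <- file.path(outdir, "manifest.json")
  jsonlite::write_json(run_manifest(config, seeds, inputs), fm,
                       auto_unbox = TRUE, digits = NA)
  written["manifest"] <- fm
  invisible(written)
}

#' Importance-profile plot
#'
#' Bar chart of mean scaled importance per feature with t-based 95%
#' confidence intervals and a dashed reference line at 10% scaled
#' importance, below which features are read as noise-level.
#'
#' @param importance A [variable_importance()] data frame.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  importance$feature <- factor(importance$feature,
                               levels = rev(importance$feature))
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = .data$feature,
                               y = .data$mean_importance)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 10, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean scaled importance (0-100)") +
    ggplot2::theme_minimal()
}

#' AUC distribution plot across model presets
#'
#' Boxplots of per-replicate validation AUCs for several fitted model
#' variants, with a dashed line at the noise-calibrated case-shuffling
#' baseline.
#'
#' @param auc_table Data frame with columns `model` and `auc`.
#' @param baseline Corrected noise baseline to mark (default 0.54).
#' @return A ggplot object.
#' @export
plot_auc_distributions <- function(auc_table, baseline = 0.54) {
  ggplot2::ggplot(auc_table, ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = baseline, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Validation AUC") +
    ggplot2::theme_minimal()
}
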