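#' Read and write variant call tables
#'
#' @description Tabular variant I/O. The TSV dialect has one row per call
#' with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `impact`,
#' `maf` (sample-level mutant allele fraction), `mac` (mutant read count),
#' `context5`, `context3` (single flanking bases on the reported strand), and
#' `flags` (semicolon-separated pass-through annotation labels, may be
#' empty). Dinucleotide events are single rows with two-base `ref`/`alt`.
#'
#' @param path File path.
#' @return `read_variants_tsv`: variant data.frame;
#'   `write_variants_tsv`: the path, invisibly.
#' @name variant_io
NULL

#' @rdname variant_io
#' @export
read_variants_tsv <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(flags = "character"))
  v$flags[is.na(v$flags)] <- ""
  check_variants(v)
  v
}

#' @rdname variant_io
#' @param variants Variant data.frame.
#' @export
write_variants_tsv <- function(variants, path) {
  check_variants(variants)
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write variant calls as VCF 4.2
#'
#' One record per sample-level call (sites are not merged across samples);
#' the owning sample and all analysis fields travel in INFO keys `SAMPLE`,
#' `GENE`, `IMPACT`, `MAF`, `MAC`, `C5`, `C3`, and `FLAGS`. Multi-allelic
#' records are never emitted. This single-call dialect keeps per-sample MAF
#' and MAC unambiguous.
#'
#' @param variants Variant data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  check_variants(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=melscreen",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample carrying the call\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Functional impact (HIGH/MODERATE/LOW/MODIFIER)\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Sample-level mutant allele fraction\">",
    "##INFO=<ID=MAC,Number=1,Type=Integer,Description=\"Mutant allele read count\">",
    "##INFO=<ID=C5,Number=1,Type=String,Description=\"5-prime flanking base\">",
    "##INFO=<ID=C3,Number=1,Type=String,Description=\"3-prime flanking base\">",
    "##INFO=<ID=FLAGS,Number=.,Type=String,Description=\"Pass-through annotation flags\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- sprintf(
    "SAMPLE=%s;GENE=%s;IMPACT=%s;MAF=%s;MAC=%d;C5=%s;C3=%s%s",
    variants$sample_id, variants$gene, variants$impact,
    formatC(variants$maf, format = "g", digits = 6), variants$mac,
    variants$context5, variants$context3,
    ifelse(nchar(variants$flags) > 0, paste0(";FLAGS=", variants$flags), "")
  )
  recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt, info)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read variant calls from VCF 4.2
#'
#' Reads the dialect of [write_variants_vcf()] (INFO keys `SAMPLE`, `GENE`,
#' `IMPACT`, `MAF`, `MAC`, `C5`, `C3`, `FLAGS`). Multi-allelic records are
#' split into one call per alternate allele before anything else. When `MAF`
#' or `MAC` INFO keys are absent, they are recovered from the first sample
#' column's `AD` (allelic depths, ref then alt) genotype field: `mac` = alt
#' depth, `maf` = alt depth / total depth.
#'
#' @param path VCF file path.
#' @param sample_id Fallback sample identifier when the `SAMPLE` INFO key is
#'   absent (e.g. per-sample VCFs); default uses the file stem.
#' @return Variant data.frame (see [read_variants_tsv()] for columns).
#' @export
read_variants_vcf <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) return(empty_variants())

  getinfo <- function(key, as = "character") {
    vcfR::extract.info(v, element = key, as.numeric = as == "numeric")
  }
  out <- data.frame(
    sample_id = getinfo("SAMPLE"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = getinfo("GENE"),
    impact = getinfo("IMPACT"),
    maf = suppressWarnings(as.numeric(getinfo("MAF"))),
    mac = suppressWarnings(as.integer(getinfo("MAC"))),
    context5 = getinfo("C5"),
    context3 = getinfo("C3"),
    flags = getinfo("FLAGS"),
    stringsAsFactors = FALSE
  )
  out$flags[is.na(out$flags)] <- ""
  out$context5[is.na(out$context5)] <- "N"
  out$context3[is.na(out$context3)] <- "N"
  if (all(is.na(out$sample_id))) {
    out$sample_id <- if (is.null(sample_id)) {
      sub("\\.vcf(\\.gz)?$", "", basename(path))
    } else {
      sample_id
    }
  }

  # split multi-allelic records into one call per alt
  multi <- grepl(",", out$alt, fixed = TRUE)
  if (any(multi)) {
    alts <- strsplit(out$alt, ",", fixed = TRUE)
    reps <- lengths(alts)
    out <- out[rep(seq_len(n), reps), , drop = FALSE]
    out$alt <- unlist(alts)
    rownames(out) <- NULL
  }

  # fall back to per-sample AD for MAF/MAC when INFO lacked them
  if (anyNA(out$maf) || anyNA(out$mac)) {
    ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
    if (!is.null(ad) && ncol(ad) >= 1) {
      parts <- strsplit(ad[, 1], ",", fixed = TRUE)
      ref_d <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
      alt_d <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
      rows <- if (exists("reps", inherits = FALSE)) rep(seq_len(n), reps) else seq_len(n)
      fill_mac <- is.na(out$mac)
      out$mac[fill_mac] <- as.integer(alt_d[rows][fill_mac])
      fill_maf <- is.na(out$maf)
      tot <- ref_d[rows] + alt_d[rows]
      out$maf[fill_maf] <- (alt_d[rows] / tot)[fill_maf]
    }
  }
  check_variants(out)
  out
}

#' Write a clinical table as TSV
#'
#' Header columns: `sample_id`, `os_dx_months`, `os_spec_months`, `event`,
#' `age_years`, `stage`, `mol_class`, `expr_class`, plus any extra columns
#' present (e.g. `burden`).
#'
#' @param clinical Clinical data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Load a simulation configuration from YAML
#'
#' The YAML keys mirror [simulation_config()] argument names; `gene_panel`
#' is a list of `{gene, prevalence, log_hr}` mappings.
#'
#' @param path YAML file path.
#' @return A validated `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$gene_panel)) {
    y$gene_panel <- do.call(rbind, lapply(y$gene_panel, function(g) {
      data.frame(gene = g$gene, prevalence = g$prevalence, log_hr = g$log_hr,
                 stringsAsFactors = FALSE)
    }))
  }
  do.call(simulation_config, y)
}
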