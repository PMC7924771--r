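#' Simulate whole-genome variant data
#'
#' Runs the sequential coalescent-with-recombination process over
#' \code{[0, L)} under the given demography (including any exponential-growth
#' epochs), drops mutations on each constant-tree segment at rate
#' \eqn{\mu B}, and returns the variant sites as an \code{\link{observation}}
#' together with a truth record (true Ne(t), true rho, and the per-window
#' mean TMRCA of the realised genealogy sequence).  Optionally writes a
#' phased (or unphased) VCF and a truth TSV.
#'
#' @param model a \code{\link{demographic_model}}.
#' @param n number of haplotypes.
#' @param L sequence length in bp.
#' @param window window size for the TMRCA truth track (bp).
#' @param unphase return/write diploid genotypes instead of phased
#'   haplotypes (n must be even).
#' @param vcf optional path: write the variants as VCF 4.2.
#' @param truth_file optional path: write the truth table as TSV.
#' @return list with \code{obs} (an observation; loci are the integer bp
#'   positions), \code{truth} (data frame: window start, mean TMRCA), and
#'   \code{n_recomb}.
#' @export
simulate_genomes <- function(model, n, L, window = 1000, unphase = FALSE,
                             vcf = NULL, truth_file = NULL) {
  if (unphase && n %% 2 != 0) stop("unphased output needs an even haplotype count")
  sim <- cpp_simulate(as.integer(n), as.numeric(L), as_engine_model(model),
                      as.numeric(window))
  loci <- floor(sim$loci)
  keep <- !duplicated(loci)
  loci <- loci[keep]
  masks <- sim$carriers[keep]
  m <- length(loci)
  pat <- matrix(0L, n, m)
  for (i in seq_len(n)) pat[i, ] <- as.integer(bitwAnd(masks %/% 2^(i - 1), 1))
  if (unphase) {
    gen <- pat[seq(1, n, by = 2), , drop = FALSE] + pat[seq(2, n, by = 2), , drop = FALSE]
    obs <- observation(loci = loci, genotypes = gen, L = L)
  } else {
    obs <- observation(loci = loci, patterns = pat, L = L)
  }
  truth <- data.frame(window_start = (seq_along(sim$tmrca) - 1) * window,
                      tmrca = sim$tmrca)
  if (!is.null(vcf)) write_vcf(obs, vcf)
  if (!is.null(truth_file)) {
    utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(obs = obs, truth = truth, n_recomb = sim$n_recomb)
}

# minimal VCF 4.2 writer for biallelic SNVs (GT only)
write_vcf <- function(obs, path, chrom = "1") {
  n <- obs$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom, ceiling(obs$L)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (obs$phased) {
    nind <- n / 2
    samples <- paste0("sample", seq_len(max(1, floor(nind))))
    if (n %% 2 != 0) samples <- paste0("hap", seq_len(n))
  } else {
    nind <- n / 2
    samples <- paste0("sample", seq_len(nind))
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  for (j in seq_along(obs$loci)) {
    if (obs$phased) {
      a <- obs$patterns[, j]
      av <- ifelse(is.na(a), ".", as.character(a))
      gt <- if (n %% 2 == 0)
        paste(av[seq(1, n, 2)], av[seq(2, n, 2)], sep = "|")
      else av
    } else {
      g <- obs$genotypes[, j]
      gt <- c("0/0", "0/1", "1/1")[g + 1]
      gt[is.na(g)] <- "./."
    }
    writeLines(paste(c(chrom, sprintf("%d", as.integer(obs$loci[j]) + 1L), ".",
                       "A", "T", ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read variant calls (VCF) and an optional observed-region mask (BED)
#'
#' Biallelic SNVs only; records with any non-SNV or extra allele are skipped
#' and counted.  Phasing is detected from the genotype separator ("|" phased,
#' "/" unphased); a mixture is read as unphased.  Positions are converted to
#' 0-based coordinates.  BED masks are 0-based half-open; sites outside the
#' mask are dropped with a warning.  An absent mask means fully observed.
#' The REF allele is taken to be ancestral; no pattern folding is applied.
#'
#' @param vcf path to a VCF file.
#' @param mask optional path to a BED file.
#' @param L sequence length; default: the contig length from the VCF header,
#'   or (max position + 1) if absent.
#' @param n expected haplotype count (checked when given).
#' @return list with \code{obs} (an \code{\link{observation}}) and
#'   \code{mask} (an \code{\link{observed_mask}} or NULL).
#' @export
read_variants <- function(vcf, mask = NULL, L = NULL, n = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ok <- nchar(fx$REF) == 1 & nchar(fx$ALT) == 1 &
    fx$REF %in% c("A", "C", "G", "T") & fx$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!ok)
  if (n_skip > 0) message("skipped ", n_skip, " non-biallelic/non-SNV record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[ok, , drop = FALSE]
  pos <- as.numeric(fx$POS[ok]) - 1
  if (is.null(L)) {
    meta <- grep("^##contig", v@meta, value = TRUE)
    len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", meta)))
    L <- if (length(len) && is.finite(len[1])) len[1] else max(pos) + 1
  }
  phased <- all(grepl("\\|", gt[!is.na(gt) & gt != "."])) && any(grepl("\\|", gt))
  nind <- ncol(gt)
  if (phased) {
    split_gt <- function(x) {
      out <- suppressWarnings(as.integer(unlist(strsplit(x, "[|]"))))
      out
    }
    pat <- matrix(NA_integer_, 2 * nind, length(pos))
    for (s in seq_len(nind)) {
      parts <- strsplit(ifelse(is.na(gt[, s]), ".|.", gt[, s]), "[|]")
      pat[2 * s - 1, ] <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
      pat[2 * s, ] <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    }
    if (!is.null(n) && n != 2 * nind)
      stop("expected ", n, " haplotypes, found ", 2 * nind)
  } else {
    gen <- matrix(NA_integer_, nind, length(pos))
    for (s in seq_len(nind)) {
      parts <- strsplit(ifelse(is.na(gt[, s]), "./.", gt[, s]), "[/|]")
      a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
      a2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
      gen[s, ] <- a1 + a2
    }
    if (!is.null(n) && n != 2 * nind)
      stop("expected ", n, " haplotypes, found ", 2 * nind)
  }
  mk <- NULL
  if (!is.null(mask)) {
    bed <- utils::read.table(mask, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    mk <- observed_mask(as.numeric(bed[[2]]), as.numeric(bed[[3]]), L)
  }
  # drop monomorphic / all-missing columns, and sites outside the mask
  if (phased) {
    keep <- colSums(pat == 1, na.rm = TRUE) >= 1
  } else {
    keep <- colSums(gen >= 1, na.rm = TRUE) >= 1
  }
  if (!is.null(mk)) {
    inm <- vapply(pos, function(s) mask_obslen(mk, s, s + 1) > 0, logical(1))
    if (any(keep & !inm)) warning(sum(keep & !inm), " site(s) outside the mask dropped")
    keep <- keep & inm
  }
  ord <- order(pos[keep])
  obs <- if (phased)
    observation(loci = pos[keep][ord], patterns = pat[, keep, drop = FALSE][, ord, drop = FALSE], L = L)
  else
    observation(loci = pos[keep][ord], genotypes = gen[, keep, drop = FALSE][, ord, drop = FALSE], L = L)
  list(obs = obs, mask = mk)
}

#' Write fit results to a directory
#'
#' Writes the per-iteration rates table (\code{rates.tsv}), the final
#' Ne-versus-time table in generations and years (\code{ne.tsv}), and a JSON
#' run manifest (\code{manifest.json}) with the settings (plus any extra
#' entries, e.g. the seed) so a run can be reproduced.
#'
#' @param fit a \code{\link{fit}} result.
#' @param outdir output directory (created if needed).
#' @param manifest named list of extra manifest entries.
#' @return \code{outdir}, invisibly.
#' @export
write_results <- function(fit, outdir, manifest = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$trace, file.path(outdir, "rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  last <- fit$trace[fit$trace$iteration == max(fit$trace$iteration) &
                      fit$trace$type == "Coal", ]
  ne_tab <- data.frame(start_gen = last$start, end_gen = last$end,
                       start_yr = last$start_yr, end_yr = last$end_yr,
                       coal_rate = last$rate, ne = last$ne)
  utils::write.table(ne_tab, file.path(outdir, "ne.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  man <- c(fit$settings, manifest,
           list(rho = fit$model$rho,
                package_version = as.character(utils::packageVersion("coalpf"))))
  jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Fast exponential for small arguments
#'
#' The continued-fraction approximation
#' \eqn{e^x \approx 1 + 2x/(2 - x + x^2/6)} for \eqn{|x| < 0.03} (relative
#' error below 1e-10), falling back to the standard exponential otherwise.
#' The compiled likelihood loops use the same function; it is exposed here
#' for inspection and testing.
#'
#' @param x numeric vector.
#' @return exp(x), approximated on the small-argument branch.
#' @export
fast_exp <- function(x) cpp_fast_exp(as.numeric(x))
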