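## End-to-end orchestration: one plain-text config drives the four
## analysis stages (marker statistics, sequence diversity + neutrality
## test + trees, chromosome LD/blocks, phenotype association) and
## writes a directory of tab-separated tables plus a run log. Stages
## without a config section are marked skipped; any stage failure
## aborts with a stage-tagged error.

#' Read a plain-text pipeline configuration
#'
#' INI-style \code{[section]} headers with \code{key = value} lines;
#' blank lines and lines starting with \code{#} are ignored. Sections:
#' \code{global} (\code{out_dir}, \code{seed}), \code{markers}
#' (\code{genotypes}, \code{min_chromosomes}), \code{sequences}
#' (\code{fasta} - semicolon-separated population FASTA paths,
#' \code{reps}), \code{trees} (\code{fasta}, \code{reps}), \code{ld}
#' (\code{haplotypes}, \code{map}, \code{maf}, \code{block_size},
#' \code{region} as \code{start-end} bp), \code{phenotypes}
#' (\code{table}, \code{response}).
#'
#' @param path Path to the config file.
#' @return Nested named list of sections.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("key outside any [section]: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      cfg[[section]][[trimws(kv[1L])]] <-
        trimws(paste(kv[-1L], collapse = "="))
    } else stop("unparseable config line: ", ln)
  }
  cfg
}

.cfgNum <- function(section, key, default) {
  v <- section[[key]]
  if (is.null(v)) default else as.numeric(v)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order and writes their
#' tables and a run log under the output directory. Every input path
#' is checked before any computation; identical configs give
#' byte-identical numeric tables (all stage seeds derive from the
#' global seed).
#'
#' @param config A config list from \code{\link{readPipelineConfig}},
#'   or a path to a config file.
#' @param outDir Output directory (default from \code{[global]
#'   out_dir}; created if absent).
#' @return Invisibly, a list describing each stage's status and output
#'   files.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  gl <- config$global %||% list()
  if (is.null(outDir)) outDir <- gl$out_dir %||% "teopop_out"
  seed <- as.integer(.cfgNum(gl, "seed", 1))
  ## validate all referenced inputs up front
  paths <- c(config$markers$genotypes,
             if (!is.null(config$sequences$fasta))
               strsplit(config$sequences$fasta, ";")[[1L]],
             if (!is.null(config$trees$fasta)) config$trees$fasta,
             config$ld$haplotypes, config$ld$map,
             config$phenotypes$table)
  for (p in paths)
    if (!file.exists(p)) stop("missing input file: ", p)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  runLog <- c(sprintf("teopop %s",
                   as.character(utils::packageVersion("teopop"))),
           sprintf("seed: %d", seed))
  status <- list()
  wt <- function(df, name) {
    f <- file.path(outDir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  runStage <- function(name, expr) {
    if (is.null(config[[name]])) {
      runLog <<- c(runLog, sprintf("stage %s: skipped (not configured)",
                             name))
      status[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    runLog <<- c(runLog, sprintf("stage %s: ok", name))
    status[[name]] <<- list(status = "ok", files = res)
  }

  runStage("markers", {
    sec <- config$markers
    minChrom <- .cfgNum(sec, "min_chromosomes", 8)
    mg <- readGenotypeTable(sec$genotypes)
    freqs <- alleleFrequencies(mg)
    fs <- hierFstats(mg, minChromosomes = minChrom)
    runLog <- c(runLog, sprintf("  min_chromosomes: %g", minChrom))
    fsTab <- data.frame(statistic = c("F_CT", "F_SC", "F_ST",
                                      "F_ST_pooled"),
                        raw = c(fs$fct, fs$fsc, fs$fst,
                                fs$fst_pooled),
                        truncated = c(fs$fct_trunc, fs$fsc_trunc,
                                      fs$fst_trunc,
                                      max(0, fs$fst_pooled)))
    c(wt(freqs, "marker_frequencies.tsv"),
      wt(fsTab, "marker_fstats.tsv"))
  })

  runStage("sequences", {
    sec <- config$sequences
    reps <- as.integer(.cfgNum(sec, "reps", 10000))
    fastas <- strsplit(sec$fasta, ";")[[1L]]
    set.seed(seed + 1L)
    rows <- lapply(fastas, function(f) {
      aln <- readFastaAlignment(f, populationLabel =
                                  sub("\\.fa(sta)?$", "", basename(f)))
      st <- diversityStats(aln)
      nt <- if (st$S >= 1 && st$n >= 4)
        tajimaNullTest(aln, reps = reps)
      else list(significant = NA, ci_low = NA_real_,
                ci_high = NA_real_)
      data.frame(population = aln@populationLabel, n = st$n,
                 S = st$S, K = st$K, H = round(st$H, 4),
                 theta_w_site = signif(st$theta_w_site, 4),
                 theta_pi_site = signif(st$theta_pi_site, 4),
                 tajima_d = round(st$tajima_d, 4),
                 d_ci_low = round(nt$ci_low, 4),
                 d_ci_high = round(nt$ci_high, 4),
                 significant = nt$significant)
    })
    wt(do.call(rbind, rows), "diversity.tsv")
  })

  runStage("trees", {
    sec <- config$trees
    reps <- as.integer(.cfgNum(sec, "reps", 10000))
    aln <- readFastaAlignment(sec$fasta)
    tr <- bootstrapSupport(aln, reps = reps, seed = seed + 2L)
    f <- file.path(outDir, "nj_tree.nwk")
    writeNewick(tr, f)
    f
  })

  runStage("ld", {
    sec <- config$ld
    maf <- .cfgNum(sec, "maf", 0.1)
    blockSize <- .cfgNum(sec, "block_size", 5000)
    hm <- readHaplotypeMatrix(sec$haplotypes, sec$map)
    hm <- mafFilter(hm, minMaf = maf)
    pairs <- pairwiseR2(hm)
    files <- wt(pairs, "ld_pairs.tsv")
    if (!is.null(sec$region)) {
      bounds <- as.numeric(strsplit(sub("^.*:", "", sec$region),
                                    "-")[[1L]])
      sm <- regionLdSummary(pairs, bounds[1L], bounds[2L])
      smTab <- data.frame(
        region = sec$region,
        mean_r2_in_region = sm$mean_r2_in_region,
        mean_r2_rest = sm$mean_r2_rest_of_chromosome,
        n_pairs_in = sm$n_pairs_in, n_pairs_rest = sm$n_pairs_rest,
        n_pairs_straddling = sm$n_pairs_straddling)
      files <- c(files, wt(smTab, "ld_region_summary.tsv"))
    }
    blocks <- buildHaplotypeBlocks(hm, blockSize = blockSize)
    c(files, wt(blocks$blocks, "haplotype_blocks.tsv"))
  })

  runStage("phenotypes", {
    sec <- config$phenotypes
    response <- sec$response %||% "tillering_index"
    pt <- readPhenotypeTable(sec$table)
    tab <- repeatedMeasuresAnova(pt, response = response)
    files <- wt(cbind(effect = rownames(tab),
                      tab[, c("ss", "df", "ms", "F", "p")]),
                "association_anova.tsv")
    rec <- phenotypeRecords(pt)
    culm <- rec[!is.na(rec$culm_diameter) &
                  rec$genotype_call %in% c("HH", "Hh", "hh"), ]
    if (nrow(culm) >= 4L &&
        length(unique(culm$genotype_call)) >= 2L) {
      cv <- onewayAnova(culm$culm_diameter, culm$genotype_call)
      files <- c(files, wt(data.frame(trait = "culm_diameter",
                                      F = cv$F, p = cv$p),
                           "culm_anova.tsv"))
    }
    files
  })

  writeLines(runLog, file.path(outDir, "run_log.txt"))
  invisible(status)
}
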