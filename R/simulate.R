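#' Simulation configuration for a synthetic bisulfite time course
#'
#' Defaults emulate a maize promoter window on day 1 of germination:
#' a 250-nt window at plant-promoter-like GC content, per-context methylation
#' probabilities 0.429 (CG), 0.833 (CNG), 0.833 (CNN), bisulfite conversion
#' efficiency 0.85 (inside the 78-88% band typical of amplicon bisulfite
#' runs), no sequencing error. `samples` defaults to a three-day germination
#' course whose per-day probabilities follow the same promoter's counts
#' (days 1, 4, 8).
#'
#' @param length Window length in nt (>= 30).
#' @param gc GC content fraction.
#' @param p_cg,p_cng,p_cnn Per-context methylation probabilities used when
#'   `samples` is not given.
#' @param efficiency Bisulfite conversion efficiency in `[0,1]`.
#' @param error_rate Per-base sequencing error rate.
#' @param samples Named list: per sample, a numeric vector
#'   `c(CG=, CNG=, CNN=)` of methylation probabilities.
#' @param seed Master integer seed; stage seeds are derived from it (see
#'   [simulate_timecourse()]).
#' @param region_id Label for the synthetic region.
#' @return A `sim_config` list.
#' @export
sim_config <- function(length = 250L, gc = 0.45,
                       p_cg = 0.429, p_cng = 0.833, p_cnn = 0.833,
                       efficiency = 0.85, error_rate = 0,
                       samples = NULL, seed = 20260101L,
                       region_id = "synthetic_promoter") {
  if (length < 30L) stop("parameter error: length must be >= 30", call. = FALSE)
  for (v in c(gc, p_cg, p_cng, p_cnn, efficiency, error_rate)) {
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("parameter error: fractions must be in [0,1]", call. = FALSE)
    }
  }
  if (is.null(samples)) {
    # day-course defaults: day-1 values above, later days from the same
    # promoter's unmethylated counts (4/36ths style arithmetic)
    samples <- list(
      "day 1" = c(CG = p_cg, CNG = p_cng, CNN = p_cnn),
      "day 4" = c(CG = 0.429, CNG = 0.667, CNN = 0.778),
      "day 8" = c(CG = 0.143, CNG = 0.833, CNN = 0.722))
  }
  samples <- lapply(samples, function(p) {
    if (!all(c("CG", "CNG", "CNN") %in% names(p))) {
      stop("each sample needs probabilities named CG, CNG, CNN", call. = FALSE)
    }
    p[c("CG", "CNG", "CNN")]
  })
  structure(list(length = as.integer(length), gc = gc,
                 efficiency = efficiency, error_rate = error_rate,
                 samples = samples, seed = as.integer(seed),
                 region_id = region_id),
            class = "sim_config")
}

#' Generate a random promoter window
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`,
#' assigned upstream coordinates `-length .. -1`. Deterministic under `seed`.
#' The i.i.d. model has no dinucleotide structure; it exercises the pipeline,
#' it does not imitate promoter composition.
#'
#' @param length Window length (>= 30).
#' @param gc GC fraction in `[0,1]`.
#' @param seed Integer seed or `NULL`.
#' @param region_id Region label.
#' @return A [ref_region] spanning `-length .. -1`.
#' @export
generate_promoter <- function(length = 250L, gc = 0.45, seed = NULL,
                              region_id = "synthetic_promoter") {
  if (length < 30L) stop("parameter error: length must be >= 30", call. = FALSE)
  if (!is.numeric(gc) || gc < 0 || gc > 1) {
    stop("parameter error: gc must be in [0,1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  ref_region(paste(bases, collapse = ""), -length, -1L,
             region_id = region_id)
}

#' Plant a random methylation state on a site map
#'
#' Each countable site is methylated independently with its context-class
#' probability. Edge-excluded sites never receive a state.
#'
#' @param sitemap A `site_map`.
#' @param p_cg,p_cng,p_cnn Per-context methylation probabilities.
#' @param seed Integer seed or `NULL`.
#' @return A [meth_state].
#' @export
plant_methylation <- function(sitemap, p_cg = 0.429, p_cng = 0.833,
                              p_cnn = 0.833, seed = NULL) {
  for (v in c(p_cg, p_cng, p_cnn)) {
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("parameter error: probabilities must be in [0,1]", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  ctx <- site_contexts(sitemap)
  p <- c(CG = p_cg, CNG = p_cng, CNN = p_cnn)[ctx]
  status <- ifelse(stats::runif(length(ctx)) < p, "methylated",
                   "unmethylated")
  meth_state(sitemap, stats::setNames(status, names(ctx)))
}

# stage seed derivation: master + fixed offset per stage, + sample index
# where per-sample (documented; keeps every stage independently reproducible)
.stage_seed <- function(master, stage, i = 0L) {
  as.integer((master + stage * 1000L + i) %% .Machine$integer.max)
}

#' Simulate a bisulfite-sequencing time course
#'
#' One synthetic promoter region, and per sample a planted methylation state
#' plus a bisulfite-converted read generated with [convert_in_silico()].
#' Every stage derives its own seed from the master seed (region: master +
#' 1000; state for sample i: master + 2000 + i; read for sample i: master +
#' 3000 + i), so each stage regenerates independently and the whole bundle is
#' byte-identical under the same config.
#'
#' @param config A [sim_config()].
#' @return A `truth_bundle`: list with `region`, `sitemap`, `states`,
#'   `reads` (named per sample) and `manifest` (config echo + stage seeds).
#' @export
simulate_timecourse <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$samples) < 1L) stop("need >= 1 sample", call. = FALSE)
  region <- generate_promoter(config$length, config$gc,
                              seed = .stage_seed(config$seed, 1L),
                              region_id = config$region_id)
  sitemap <- find_cytosine_sites(region)
  states <- list()
  reads <- list()
  labels <- names(config$samples)
  for (i in seq_along(config$samples)) {
    p <- config$samples[[i]]
    states[[labels[i]]] <- plant_methylation(
      sitemap, p[["CG"]], p[["CNG"]], p[["CNN"]],
      seed = .stage_seed(config$seed, 2L, i))
    reads[[labels[i]]] <- convert_in_silico(
      region, sitemap, states[[labels[i]]],
      efficiency = config$efficiency, error_rate = config$error_rate,
      seed = .stage_seed(config$seed, 3L, i),
      read_id = paste0(config$region_id, "_", gsub("\\s+", "", labels[i])))
  }
  cfg_out <- unclass(config)
  cfg_out$samples <- lapply(cfg_out$samples, as.list)
  manifest <- list(
    config = cfg_out,
    stage_seeds = list(
      region = .stage_seed(config$seed, 1L),
      states = stats::setNames(
        lapply(seq_along(labels), function(i) .stage_seed(config$seed, 2L, i)),
        labels),
      reads = stats::setNames(
        lapply(seq_along(labels), function(i) .stage_seed(config$seed, 3L, i)),
        labels)))
  structure(list(region = region, sitemap = sitemap, states = states,
                 reads = reads, manifest = manifest),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("<truth_bundle> ", x$region$region_id, ", ",
      nchar(x$region$sequence), " nt, samples: ",
      paste(names(x$reads), collapse = ", "), "\n", sep = "")
  print(x$sitemap)
  invisible(x)
}

#' Write a truth bundle to disk as plain-text fixtures
#'
#' Writes `reference.fasta`, `reads.fasta` (one record per sample),
#' `sitemap.tsv`, `truth.tsv` (sample, position, status) and
#' `manifest.json` (config, stage seeds, md5 checksums of the data files).
#' [read_fixture_bundle()] verifies the checksums and reconstructs the
#' bundle.
#'
#' @param bundle A `truth_bundle`.
#' @param directory Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_fixture_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "truth_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, c("reference.fasta", "reads.fasta",
                                  "sitemap.tsv", "truth.tsv"))
  names(paths) <- basename(paths)
  ref <- Biostrings::DNAStringSet(
    stats::setNames(bundle$region$sequence, bundle$region$region_id))
  Biostrings::writeXStringSet(ref, paths[["reference.fasta"]])
  reads <- Biostrings::DNAStringSet(
    stats::setNames(vapply(bundle$reads, function(r) r$sequence, character(1)),
                    names(bundle$reads)))
  Biostrings::writeXStringSet(reads, paths[["reads.fasta"]])
  write_sitemap_tsv(bundle$sitemap, paths[["sitemap.tsv"]])
  truth <- do.call(rbind, lapply(names(bundle$states), function(s) {
    st <- bundle$states[[s]]$status
    data.frame(sample = s, position = as.integer(names(st)),
               status = unname(st), stringsAsFactors = FALSE)
  }))
  utils::write.table(truth, paths[["truth.tsv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- bundle$manifest
  manifest$window <- c(bundle$region$upstream_start,
                       bundle$region$upstream_end)
  manifest$checksums <- as.list(tools::md5sum(unname(paths)))
  names(manifest$checksums) <- names(paths)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(directory)
}

#' Read back a fixture bundle, verifying checksums
#'
#' @param directory Directory written by [write_fixture_bundle()].
#' @return A `truth_bundle` equal to the one written.
#' @export
read_fixture_bundle <- function(directory) {
  mpath <- file.path(directory, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in '", directory, "'",
                                call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  for (f in names(manifest$checksums)) {
    p <- file.path(directory, f)
    got <- unname(tools::md5sum(p))
    if (is.na(got) || got != manifest$checksums[[f]]) {
      stop("checksum mismatch for '", f, "': expected ",
           manifest$checksums[[f]], ", got ", got, call. = FALSE)
    }
  }
  win <- as.integer(manifest$window)
  region <- load_reference(file.path(directory, "reference.fasta"),
                           win[1], win[2])
  region$region_id <- manifest$config$region_id
  sitemap <- find_cytosine_sites(region)
  truth <- utils::read.table(file.path(directory, "truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  labels <- names(manifest$config$samples)
  states <- lapply(labels, function(s) {
    d <- truth[truth$sample == s, ]
    meth_state(sitemap, stats::setNames(d$status, d$position))
  })
  names(states) <- labels
  readset <- Biostrings::readDNAStringSet(file.path(directory, "reads.fasta"))
  reads <- lapply(labels, function(s) {
    structure(list(
      read_id = paste0(manifest$config$region_id, "_", gsub("\\s+", "", s)),
      sequence = as.character(readset[[s]]),
      provenance = "simulated",
      conversion_efficiency_used = manifest$config$efficiency,
      error_rate_used = manifest$config$error_rate,
      rng_seed = as.integer(manifest$stage_seeds$reads[[s]])),
      class = "bs_read")
  })
  names(reads) <- labels
  structure(list(region = region, sitemap = sitemap, states = states,
                 reads = reads, manifest = manifest),
            class = "truth_bundle")
}

#' Rebuild a simulation from a manifest alone
#'
#' Reconstructs the [sim_config()] recorded in a bundle manifest and re-runs
#' [simulate_timecourse()]; under the recorded seeds the regenerated reads are
#' byte-identical to the stored ones.
#'
#' @param manifest Manifest list or path to a `manifest.json`.
#' @return A `truth_bundle`.
#' @export
regenerate_bundle <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  cfg <- manifest$config
  config <- sim_config(length = cfg$length, gc = cfg$gc,
                       efficiency = cfg$efficiency,
                       error_rate = cfg$error_rate,
                       samples = lapply(cfg$samples, unlist),
                       seed = cfg$seed, region_id = cfg$region_id)
  simulate_timecourse(config)
}
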