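#' Read and validate a pipeline configuration
#'
#' YAML keys (defaults in parentheses): \code{input_fasta},
#' \code{labeled_corpus}, \code{output_dir}, \code{seed} (1),
#' \code{min_orf_nt} (30), \code{enzymes}
#' (\code{trypsin, chymotrypsin-high}), \code{max_missed} (0),
#' \code{min_len_aa} (4), \code{max_len_aa} (15),
#' \code{identity_threshold} (0.9), \code{top_n} (10),
#' \code{threshold} (0.5), \code{epochs} (200), \code{explain}
#' (TRUE), \code{explain_samples} (50).
#'
#' @param config path to a YAML file or a named list.
#' @return Validated config list with defaults filled in.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, min_orf_nt = 30L,
                   enzymes = c("trypsin", "chymotrypsin-high"),
                   max_missed = 0L, min_len_aa = 4L, max_len_aa = 15L,
                   identity_threshold = 0.9, top_n = 10L,
                   threshold = 0.5, epochs = 200L, explain = TRUE,
                   explain_samples = 50L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("input_fasta", "labeled_corpus", "output_dir"))
    if (is.null(config[[nm]])) stop("config key '", nm, "' is required")
  for (nm in c("input_fasta", "labeled_corpus"))
    if (!file.exists(config[[nm]]))
      stop("config path does not exist: ", config[[nm]])
  stopifnot(config$top_n >= 1)
  config
}

#' Run the umami peptide discovery pipeline
#'
#' Orchestrates ORF extraction, combined proteolysis, redundancy
#' removal, ensemble training and prediction, candidate ranking,
#' physicochemical annotation and (optionally) Shapley attribution of
#' the candidates. Every stage writes its artifact into
#' \code{output_dir}; a JSON manifest records parameters, seeds and
#' per-stage record counts. Ranking keeps unanimous positives only,
#' ordered by average probability (ties broken by sequence) — a rerun
#' with identical config and seed reproduces the candidate table
#' byte-for-byte.
#'
#' @param config path to a YAML config or a named list; see
#'   [pipelineConfig()].
#' @return Invisibly, the candidate data.frame (also written to
#'   \code{candidates.tsv}).
#' @export
runPipeline <- function(config) {
  cfg <- pipelineConfig(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(cfg$output_dir, f)
  counts <- list()

  ## stage 1: input
  dna <- tryCatch(readNucleotideFasta(cfg$input_fasta),
                  error = function(e)
                    stop("stage 1 (read input): ", conditionMessage(e),
                         call. = FALSE))
  counts$input_records <- length(dna)

  ## stage 2: ORFs
  orfs <- findOrfs(dna, minLenNt = cfg$min_orf_nt)
  if (length(orfs) == 0L)
    stop("stage 2 (ORF extraction): no ORFs of >= ", cfg$min_orf_nt,
         " nt found", call. = FALSE)
  writeProteinFasta(orfs, art("orfs.faa"))
  counts$orfs <- length(orfs)

  ## stage 3: digestion
  mc <- S4Vectors::mcols(orfs)
  prot <- setNames(as.character(orfs),
                   sprintf("%s|%+d|%d-%d", mc$parent_id, mc$frame,
                           mc$start_nt, mc$end_nt))
  params <- digestParams(
    rules = lapply(cfg$enzymes, enzymePreset),
    maxMissedCleavages = cfg$max_missed,
    minLenAa = cfg$min_len_aa, maxLenAa = cfg$max_len_aa)
  peptides <- digestProteins(prot, params)
  if (nrow(peptides) == 0L)
    stop("stage 3 (digestion): no peptides in the length window",
         call. = FALSE)
  utils::write.table(peptides, art("peptides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts$peptides <- nrow(peptides)

  ## stage 4: redundancy removal
  clustering <- clusterPeptides(unique(peptides$sequence),
                                threshold = cfg$identity_threshold)
  writeClusters(clustering, art("representatives.fasta"),
                art("clusters.tsv"))
  reps <- clustering$representatives
  counts$representatives <- length(reps)

  ## stage 5: ensemble training
  corpus <- loadLabeledPeptides(cfg$labeled_corpus)
  maxLen <- max(nchar(c(corpus$sequence, reps)))
  enc <- encodingSpec(maxLen)
  ens <- trainEnsemble(corpus$sequence, corpus$label, encoding = enc,
                       seed = cfg$seed, epochs = cfg$epochs,
                       threshold = cfg$threshold, quiet = TRUE)
  counts$training_peptides <- nrow(corpus)

  ## stage 6: prediction
  pred <- ensemblePredict(ens, reps)
  pred <- pred[order(-pred$average_prob, pred$sequence), ,
               drop = FALSE]
  .writeNumTable(pred, art("predictions.tsv"))
  counts$unanimous_positives <- sum(pred$unanimous)

  ## stage 7: candidate ranking + annotation
  cand <- pred[pred$unanimous, , drop = FALSE]
  cand <- utils::head(cand, cfg$top_n)
  if (nrow(cand)) {
    cand$rank <- seq_len(nrow(cand))
    phys <- physChemProfile(cand$sequence)
    cand <- cbind(cand[c("rank", "sequence", "p_cnn", "p_lstm",
                         "p_attention", "p_transformer",
                         "average_prob", "unanimous")],
                  phys[c("mw", "pI", "gravy", "charge", "toxicity")])
  }
  .writeNumTable(cand, art("candidates.tsv"))
  counts$candidates <- nrow(cand)

  ## stage 8: attribution of the candidates
  if (isTRUE(cfg$explain) && nrow(cand)) {
    attrRows <- lapply(seq_len(nrow(cand)), function(i) {
      pep <- cand$sequence[i]
      at <- if (nchar(pep) <= 12L)
        shapleyPositions(ens, pep, mode = "exact")
      else shapleyPositions(ens, pep, mode = "sampled",
                            nSamples = cfg$explain_samples,
                            seed = cfg$seed + i)
      data.frame(sequence = pep, feature = names(at@values),
                 value = unname(at@values), base = at@baseValue,
                 prediction = at@prediction, mode = at@mode,
                 stringsAsFactors = FALSE)
    })
    .writeNumTable(do.call(rbind, attrRows), art("attributions.tsv"))
  }

  ## manifest (no timestamps: reruns must be byte-identical)
  manifest <- list(package = "UmamiForge",
                   version = as.character(utils::packageVersion("UmamiForge")),
                   config = cfg[order(names(cfg))], counts = counts)
  jsonlite::write_json(manifest, art("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf(
    "pipeline done: %d records -> %d ORFs -> %d peptides -> %d reps -> %d candidates",
    counts$input_records, counts$orfs, counts$peptides,
    counts$representatives, counts$candidates))
  invisible(cand)
}

# write a table with fixed 15-significant-digit formatting so that
# numerically identical reruns are byte-identical
.writeNumTable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (nm in names(df)[num]) df[[nm]] <- sprintf("%.15g", df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
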