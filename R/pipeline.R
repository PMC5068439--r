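# Orchestration of the full analysis: simulate (or load) -> supermatrix ->
# ML/BI -> per-gene classification -> concordance -> diagnostics, with one
# seed stream per stage.

#' Pipeline configuration
#'
#' @param scenario a [scenario_spec()] (exactly one of `scenario` /
#'   `input_dir` must be set).
#' @param input_dir directory of per-gene FASTA files (`*.nt.fasta` with
#'   matching `*.aa.fasta`) plus a `groups.tsv` (taxon, group).
#' @param nt_model,aa_model substitution models for the two data types.
#' @param partition_schemes schemes evaluated for the supermatrix grid.
#' @param bootstrap_reps bootstrap replicates for the ML analyses.
#' @param mcmc an [mcmc_settings()] for the supermatrix Bayesian analyses.
#' @param gene_mcmc an [mcmc_settings()] for the per-gene Bayesian
#'   analyses (also feeds the concordance factors).
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; each stage derives its own stream from it.
#' @param verbose print stage progress to standard error.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(scenario = NULL, input_dir = NULL,
                            nt_model = substitution_model(
                              "nucleotide", "GTR", gamma_shape = 0.7,
                              p_inv = 0.1),
                            aa_model = substitution_model(
                              "amino_acid", "JTT", gamma_shape = 0.7,
                              p_inv = 0.1),
                            partition_schemes = c("unpartitioned", "by_gene",
                                                  "by_codon"),
                            bootstrap_reps = 100,
                            mcmc = mcmc_settings(n_generations = 5e4,
                                                 sample_every = 50,
                                                 n_runs = 2),
                            gene_mcmc = mcmc_settings(n_generations = 2e3,
                                                      sample_every = 10,
                                                      n_runs = 1),
                            out_dir = tempfile("pipeline"), seed = 1,
                            verbose = TRUE) {
  if (is.null(scenario) == is.null(input_dir))
    stop("set exactly one of scenario / input_dir")
  structure(list(scenario = scenario, input_dir = input_dir,
                 nt_model = nt_model, aa_model = aa_model,
                 partition_schemes = partition_schemes,
                 bootstrap_reps = bootstrap_reps, mcmc = mcmc,
                 gene_mcmc = gene_mcmc, out_dir = out_dir,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + match(stage, c(
    "data", "supermatrix", "ml", "mcmc", "genes", "concordance",
    "diagnostics", "summary")) * 10007L) %% 2147483562L
}

.say <- function(config, ...) {
  if (config$verbose) message(sprintf(...))
}

run_stage <- function(config, name, fn) {
  tryCatch(fn(), error = function(e)
    stop("pipeline stage '", name, "' failed (seed ",
         stage_seed(config$seed, name), "): ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writes per-stage artifacts to
#' `config$out_dir` (gene FASTAs and manifest, supermatrix NEXUS and
#' partition files, ML trees with bootstrap supports, consensus trees,
#' pattern table, concordance factors, composition and saturation reports)
#' and returns a summary grid naming the supported hypothesis per analysis
#' ({ml, bi} x {aa, nt} x partition scheme).
#'
#' @param config a [pipeline_config()].
#' @return list (invisibly) with `summary` (the analysis grid),
#'   `pattern_table`, `length_test`, `concordance`, `composition`,
#'   `saturation` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- data ----------------------------------------------------------------
  gs <- run_stage(config, "data", function() {
    set.seed(stage_seed(config$seed, "data"))
    if (!is.null(config$scenario)) {
      sp <- config$scenario
      sp$seed <- stage_seed(config$seed, "data")
      m <- resolve_nt_model(config$nt_model)
      simulate_gene_set(sp, m)
    } else {
      read_gene_set(config$input_dir)
    }
  })
  .say(config, "data: %d genes, %d taxa", nrow(gs$manifest),
       length(gs$groups))
  write_gene_set(gs, file.path(config$out_dir, "genes"), config$seed)

  # ---- supermatrix ---------------------------------------------------------
  sm <- run_stage(config, "supermatrix", function() {
    nt <- concatenate(stats::setNames(lapply(gs$genes, `[[`, "nt"),
                                      gs$manifest$gene))
    aa <- concatenate(stats::setNames(lapply(gs$genes, `[[`, "aa"),
                                      gs$manifest$gene))
    write_alignment(nt$alignment,
                    file.path(config$out_dir, "supermatrix_nt.nex"),
                    "nexus")
    write_alignment(aa$alignment,
                    file.path(config$out_dir, "supermatrix_aa.nex"),
                    "nexus")
    for (sch in intersect(config$partition_schemes, c("by_gene",
                                                      "by_codon"))) {
      ps <- build_partitions(nt, sch)
      write_partitions(ps, file.path(config$out_dir,
                                     sprintf("partitions_nt_%s.txt", sch)),
                       "raxml", "DNA")
    }
    list(nt = nt, aa = aa)
  })
  .say(config, "supermatrix: nt %d columns, aa %d columns",
       n_columns(sm$nt$alignment), n_columns(sm$aa$alignment))

  grid <- list()
  add_cell <- function(method, data, scheme, call, support) {
    grid[[length(grid) + 1]] <<- data.frame(
      method = method, data = data, scheme = scheme,
      supported = call, min_critical_support = support)
  }
  crit <- critical_nodes(gs$groups)

  # ---- supermatrix ML ------------------------------------------------------
  run_stage(config, "ml", function() {
    for (data_type in c("nt", "aa")) {
      aln <- sm[[data_type]]$alignment
      model <- if (data_type == "nt") resolve_nt_model(config$nt_model)
               else config$aa_model
      for (sch in config$partition_schemes) {
        if (sch == "by_codon" && data_type == "aa") next
        part <- if (sch == "unpartitioned") NULL
                else build_partitions(sm[[data_type]], sch)
        tr <- bootstrap_support(aln, model, config$bootstrap_reps,
                                seed = stage_seed(config$seed, "ml"),
                                partition = part)
        write_tree(tr, file.path(config$out_dir,
                                 sprintf("ml_%s_%s.nwk", data_type, sch)))
        supp <- critical_node_support(tr, crit)
        add_cell("ml", data_type, sch,
                 classify_topology(tr, gs$groups), min(supp))
        .say(config, "ml/%s/%s: %s (min critical support %s)", data_type,
             sch, classify_topology(tr, gs$groups), min(supp))
      }
    }
  })

  # ---- supermatrix BI ------------------------------------------------------
  bi <- run_stage(config, "mcmc", function() {
    out <- list()
    for (data_type in c("nt", "aa")) {
      aln <- sm[[data_type]]$alignment
      model <- if (data_type == "nt") resolve_nt_model(config$nt_model)
               else config$aa_model
      st <- config$mcmc
      st$seed <- stage_seed(config$seed, "mcmc") + match(data_type,
                                                         c("nt", "aa"))
      res <- mcmc_run(aln, model, st)
      cons <- consensus_tree(res)
      diag <- convergence_diagnostics(res)
      write_tree(cons, file.path(config$out_dir,
                                 sprintf("bi_%s_consensus.nwk", data_type)),
                 support_as = "probability")
      supp <- critical_node_support(cons, crit, scale = 1)
      add_cell("bi", data_type, "unpartitioned",
               classify_topology(cons, gs$groups), min(supp))
      .say(config, "bi/%s: %s (min critical PP %.3f, maxdiff %.3f)",
           data_type, classify_topology(cons, gs$groups), min(supp),
           diag$maxdiff)
      out[[data_type]] <- list(result = res, consensus = cons,
                               diagnostics = diag)
    }
    out
  })

  # ---- per-gene trees, pattern table, concordance --------------------------
  genes <- run_stage(config, "genes", function() {
    nt_model <- resolve_nt_model(config$nt_model)
    seed0 <- stage_seed(config$seed, "genes")
    calls <- list()
    samples <- vector("list", length(gs$genes))
    for (g in seq_along(gs$genes)) {
      nt <- gs$genes[[g]]$nt
      aa <- gs$genes[[g]]$aa
      ml_nt <- search_ml_tree(nt, nt_model, seed = seed0 + g)
      ml_aa <- search_ml_tree(aa, config$aa_model, seed = seed0 + g)
      st <- config$gene_mcmc
      st$seed <- seed0 + g
      bi_nt <- mcmc_run(nt, nt_model, st)
      cons <- consensus_tree(bi_nt)
      samples[[g]] <- pooled_sample(bi_nt)
      samples[[g]]$gene_name <- gs$manifest$gene[g]
      calls[[g]] <- c(ml_nt = classify_topology(ml_nt$tree, gs$groups),
                      ml_aa = classify_topology(ml_aa$tree, gs$groups),
                      bi_nt = classify_topology(cons, gs$groups))
    }
    call_mat <- do.call(rbind, calls)
    rownames(call_mat) <- gs$manifest$gene
    tab <- pattern_table(call_mat, 3 * gs$manifest$n_codons)
    utils::write.table(tab, file.path(config$out_dir, "pattern_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(table = tab, samples = samples,
         length_test = length_comparison(tab))
  })

  conc <- run_stage(config, "concordance", function() {
    seedc <- stage_seed(config$seed, "concordance")
    cf1 <- sample_wide_cf(genes$samples, crit$node1, seed = seedc)
    cf_scler <- sample_wide_cf(genes$samples,
                               scleractinia_taxa(gs$groups), seed = seedc)
    pct <- primary_concordance_tree(genes$samples, seed = seedc)
    write_tree(pct, file.path(config$out_dir, "primary_concordance.nwk"),
               support_as = "probability")
    tsv <- data.frame(
      clade = c("corallimorpharia+scleractinia", "scleractinia"),
      cf = c(cf1$cf, cf_scler$cf),
      lo = c(cf1$ci[1], cf_scler$ci[1]),
      hi = c(cf1$ci[2], cf_scler$ci[2]))
    utils::write.table(tsv, file.path(config$out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(node1 = cf1, scleractinia = cf_scler, tree = pct)
  })
  .say(config, "concordance: CF(scleractinia) = %.3f",
       conc$scleractinia$cf)

  diagn <- run_stage(config, "diagnostics", function() {
    prof <- composition_profile(sm$nt$alignment, gs$groups)
    hom <- composition_homogeneity_test(sm$nt$alignment)
    sat <- saturation_test(sm$nt$alignment,
                           seed = stage_seed(config$seed, "diagnostics"))
    utils::write.table(prof$per_taxon,
                       file.path(config$out_dir, "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(profile = prof, homogeneity = hom, saturation = sat)
  })

  summary_df <- do.call(rbind, grid)
  utils::write.table(summary_df, file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(summary = summary_df, pattern_table = genes$table,
                 length_test = genes$length_test, concordance = conc,
                 bayesian = bi, composition = diagn$profile,
                 homogeneity = diagn$homogeneity,
                 saturation = diagn$saturation, out_dir = config$out_dir))
}

# a GTR model needs frequencies before simulation; default to uniform-ish
# coral-like composition when none are set
resolve_nt_model <- function(model) {
  if (is.null(model$freqs)) {
    model$freqs <- stats::setNames(c(0.28, 0.22, 0.22, 0.28), NT_STATES)
  }
  model
}

critical_node_support <- function(tree, crit, scale = 100) {
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  vapply(crit, function(cl) {
    cl <- intersect(cl, labs)
    key <- split_key(cl, labs)
    for (i in seq_along(pp)) {
      side <- labs[pp[[i]]]
      if (ref %in% side) side <- setdiff(labs, side)
      if (identical(paste(sort(side), collapse = "|"), key)) {
        lab <- tree$node.label[i]
        v <- suppressWarnings(as.numeric(lab))
        return(if (is.na(v)) 0 else v)
      }
    }
    0
  }, 0)
}

write_gene_set <- function(gs, dir, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in gs$genes) {
    write_alignment(g$nt, file.path(dir, paste0(g$nt$source_name,
                                                ".nt.fasta")))
    write_alignment(g$aa, file.path(dir, paste0(g$nt$source_name,
                                                ".aa.fasta")))
  }
  mf <- gs$manifest
  utils::write.table(mf, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gr <- data.frame(taxon = names(gs$groups),
                   group = unname(unclass(gs$groups)))
  utils::write.table(gr, file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# gene set written with master seed %d", seed),
             file.path(dir, "README.txt"))
  invisible(dir)
}

read_gene_set <- function(dir) {
  gr <- utils::read.table(file.path(dir, "groups.tsv"), header = TRUE,
                          sep = "\t")
  groups <- taxon_groups(stats::setNames(gr$group, gr$taxon))
  nts <- sort(list.files(dir, "\\.nt\\.fasta$", full.names = TRUE))
  if (!length(nts)) stop("no *.nt.fasta gene files in ", dir)
  genes <- lapply(nts, function(f) {
    nt <- read_alignment(f, "fasta", alphabet = "nucleotide")
    nt$source_name <- sub("\\.nt\\.fasta$", "", basename(f))
    nt$codon_positions <- rep(1:3, length.out = n_columns(nt))
    aaf <- sub("\\.nt\\.fasta$", ".aa.fasta", f)
    aa <- if (file.exists(aaf))
      read_alignment(aaf, "fasta", alphabet = "amino_acid")
    else aa_companion(nt)
    aa$source_name <- nt$source_name
    list(nt = nt, aa = aa, label = NA_character_,
         n_codons = n_columns(nt) / 3)
  })
  manifest <- data.frame(
    gene = vapply(genes, function(g) g$nt$source_name, ""),
    n_codons = vapply(genes, function(g) g$n_codons, 0),
    n_nt = vapply(genes, function(g) n_columns(g$nt), 0),
    label = NA_character_)
  structure(list(genes = genes, groups = groups, trees = NULL,
                 manifest = manifest), class = "gene_set")
}
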