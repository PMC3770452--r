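# Analysis reports tying the five tests together, with JSON serialisation
# and the back end of the command-line front end (inst/cli/nestedhom.R).

#' Run the full nested-homogeneity analysis of one table
#'
#' Computes every headline quantity for a 2x3 genotype table: the genotypic
#' chi-square p-value, the usual (doubled-sample) allelic p-value, the
#' corrected allelic p-value, the genotypic and allelic e-values (shared
#' posterior draws), and per-group Hardy-Weinberg p-values and e-values.
#' Flags any level-`alpha` p-value incoherence and always restates the
#' usual test's HWE validity caveat. Every stochastic quantity carries its
#' seed and replicate count, so a report can be regenerated exactly.
#'
#' @param x a [genotype_table()].
#' @param method `"mc"` (default: parametric-bootstrap corrected allelic
#'   p-value) or `"asymptotic"`.
#' @param n_reps bootstrap replicates for the corrected allelic test.
#' @param n_draws posterior draws per e-value.
#' @param prior a [dirichlet_prior()].
#' @param alpha level used for the incoherence flags.
#' @param seed master seed; substreams are derived per quantity.
#' @return An object of class `analysis_report`.
#' @examples
#' gt <- genotype_table(c(55, 83, 50), c(24, 42, 39))
#' run_analysis(gt, n_reps = 2000, n_draws = 5000, seed = 1)
#' @export
run_analysis <- function(x, method = c("mc", "asymptotic"),
                         n_reps = 10000, n_draws = 100000,
                         prior = dirichlet_prior(), alpha = 0.05,
                         seed = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  method <- match.arg(method)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  sub <- with_seed(seed, sample.int(2^31 - 2, 4))

  g <- genotypic_test(x)
  u <- allelic_test_usual(x)
  a <- if (method == "mc") {
    allelic_test_corrected(x, "mc", n_reps = n_reps, seed = sub[1])
  } else {
    allelic_test_corrected(x)
  }
  ev <- evalue_pair(x, prior = prior, n_draws = n_draws, seed = sub[2])
  hw <- lapply(c(case = "case", control = "control"), function(gr) {
    p <- tryCatch(hwe_test(x, gr)$p.value, error = function(e) NA_real_)
    e <- evalue(x, paste0("hwe_", gr), prior = prior, n_draws = n_draws,
                seed = if (gr == "case") sub[3] else sub[4])
    list(p = p, evalue = e$evalue, mc_se = e$mc_se, seed = e$seed)
  })

  warnings <- u$warning
  inc_usual <- u$p.value <= alpha && g$p.value > alpha
  inc_corr <- a$p.value <= alpha && g$p.value > alpha
  if (inc_usual || inc_corr) {
    warnings <- c(warnings, sprintf(
      "p-value incoherence at alpha = %s: an allelic test rejects while the genotypic test accepts",
      format(alpha)))
  }

  structure(
    list(table = list(case = as.numeric(x$case),
                      control = as.numeric(x$control),
                      n = x$n, m = x$m),
         genotypic = list(statistic = g$statistic, df = g$df,
                          p = g$p.value, method = g$method),
         usual_allelic = list(statistic = u$statistic, df = u$df,
                              p = u$p.value, method = u$method),
         corrected_allelic = list(statistic = a$statistic, df = a$df,
                                  p = a$p.value, method = a$method,
                                  n_reps = a$n_reps, mc_ci = a$mc_ci,
                                  seed = a$seed),
         evalues = list(genotypic = ev$genotypic$evalue,
                        allelic = ev$allelic$evalue,
                        mc_se = c(ev$genotypic$mc_se, ev$allelic$mc_se),
                        n_draws = n_draws, seed = ev$genotypic$seed),
         hwe = hw,
         prior = list(a = as.numeric(prior$a), b = as.numeric(prior$b)),
         alpha = alpha,
         incoherence = list(usual = inc_usual, corrected = inc_corr,
                            evalue = ev$genotypic$evalue >
                              ev$allelic$evalue),
         warnings = warnings,
         seed = seed,
         version = as.character(utils::packageVersion("nestedhom")),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, digits = 3, ...) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  cat("Nested homogeneity analysis (case n =", x$table$n,
      ", control m =", x$table$m, ")\n\n")
  cat(sprintf("  %-28s %-10s %-10s\n", "", "p-value", "e-value"))
  cat(sprintf("  %-28s %-10s %-10s\n", "Genotypic homogeneity",
              f(x$genotypic$p), f(x$evalues$genotypic)))
  cat(sprintf("  %-28s %-10s %-10s\n", "Allelic (usual, biased)",
              f(x$usual_allelic$p), ""))
  cat(sprintf("  %-28s %-10s %-10s\n", "Allelic (corrected)",
              f(x$corrected_allelic$p), f(x$evalues$allelic)))
  cat(sprintf("  %-28s %-10s %-10s\n", "HWE, case group",
              f(x$hwe$case$p), f(x$hwe$case$evalue)))
  cat(sprintf("  %-28s %-10s %-10s\n", "HWE, control group",
              f(x$hwe$control$p), f(x$hwe$control$evalue)))
  cat("\n  seed:", x$seed, " corrected-test method:",
      x$corrected_allelic$method, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Serialise a report to JSON
#'
#' @param report an `analysis_report`, `audit_report` or `power_table`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- if (inherits(report, "analysis_report")) {
    unclass(report)
  } else if (inherits(report, "audit_report")) {
    list(results = report$results, alpha = report$alpha,
         n_p_incoherent = report$n_p_incoherent,
         n_e_violations = report$n_e_violations, seed = report$seed)
  } else if (inherits(report, "power_table")) {
    list(scenario = attr(report, "scenario"),
         rates = as.data.frame(report))
  } else {
    stop("unsupported report class", call. = FALSE)
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Run a power study from a configuration list or file
#'
#' @param config either a named list or a path to a YAML/JSON file with
#'   entries `gamma_AA`, `gamma_AB`, `pi_AA` and optionally `eps_grid`,
#'   `tests`, `alpha`, `n_datasets`, `n`, `m`, `seed`.
#' @return A `power_table` (see [power_curve()]).
#' @export
run_power <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config),
            all(c("gamma_AA", "gamma_AB", "pi_AA") %in% names(config)))
  args <- config[intersect(names(config),
                           names(formals(power_curve)))]
  do.call(power_curve, args)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

#' Audit tables read from files
#'
#' @param paths character vector of table files (dialect of
#'   [read_genotype_table()]); unreadable files are skipped with a warning.
#' @param alpha,n_draws,seed passed to [coherence_audit()].
#' @return An `audit_report`.
#' @export
run_audit <- function(paths, alpha = 0.05, n_draws = 10000, seed = 1) {
  tabs <- list()
  for (p in paths) {
    t <- tryCatch(read_genotype_table(p), error = function(e) {
      warning("skipping ", p, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(t)) tabs[[length(tabs) + 1L]] <- t
  }
  if (!length(tabs)) stop("no readable tables", call. = FALSE)
  coherence_audit(tabs, alpha = alpha, n_draws = n_draws, seed = seed)
}
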