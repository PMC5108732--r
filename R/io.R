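read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(what, " file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  d
}

#' Read AHP judgments from CSV
#'
#' Long format, one row per elicited upper-triangle pair: columns
#' `respondent_id`, `block_id`, `row_id`, `col_id`, `value` (how many times
#' the row criterion dominates the column criterion; the reciprocal is
#' implied). In strict mode any invalid row aborts with its line number;
#' lenient mode drops invalid rows and reports them in the
#' `"problems"` attribute.
#'
#' @param path CSV path.
#' @param hierarchy A [criteria_hierarchy()] used for id validation.
#' @param strict Abort on the first bad row (default) or collect and drop.
#' @return Validated judgment data frame.
#' @export
read_judgments <- function(path, hierarchy, strict = TRUE) {
  d <- read_csv_checked(
    path, c("respondent_id", "block_id", "row_id", "col_id", "value"),
    "judgment")
  ids <- hierarchy$nodes$id
  problems <- character(0)
  bad <- logical(nrow(d))
  for (k in seq_len(nrow(d))) {
    msg <- NULL
    if (!d$block_id[k] %in% names(hierarchy$blocks)) {
      msg <- paste0("unknown block '", d$block_id[k], "'")
    } else if (!d$row_id[k] %in% ids || !d$col_id[k] %in% ids) {
      msg <- paste0("unknown criterion '",
                    setdiff(c(d$row_id[k], d$col_id[k]), ids)[1], "'")
    } else if (!is.finite(suppressWarnings(as.numeric(d$value[k]))) ||
               as.numeric(d$value[k]) <= 0) {
      msg <- paste0("malformed value '", d$value[k], "'")
    }
    if (!is.null(msg)) {
      line <- k + 1L  # header line is 1
      if (strict) stop("judgment file ", path, ", line ", line, ": ", msg)
      problems <- c(problems, paste0("line ", line, ": ", msg))
      bad[k] <- TRUE
    }
  }
  d$value <- as.numeric(d$value)
  dup <- duplicated(d[c("respondent_id", "block_id", "row_id", "col_id")]) & !bad
  if (any(dup)) {
    if (strict) {
      stop("judgment file ", path, ", line ", which(dup)[1] + 1L,
           ": duplicate judgment")
    }
    problems <- c(problems, paste0("line ", which(dup) + 1L, ": duplicate judgment"))
    bad <- bad | dup
  }
  out <- d[!bad, , drop = FALSE]
  attr(out, "problems") <- problems
  out
}

#' Read a BWS design from CSV
#' @param path CSV with columns `set_id`, `block_id`, `item_id`.
#' @param hierarchy Optional [criteria_hierarchy()] for id validation.
#' @return Design data frame.
#' @export
read_bws_design <- function(path, hierarchy = NULL) {
  d <- read_csv_checked(path, c("set_id", "block_id", "item_id"), "BWS design")
  if (!is.null(hierarchy)) {
    unknown <- setdiff(unique(d$item_id), hierarchy$nodes$id)
    if (length(unknown)) {
      stop("BWS design references unknown criterion id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  d
}

#' Read BWS choices from CSV
#' @param path CSV with columns `respondent_id`, `set_id`, `best_id`,
#'   `worst_id`.
#' @return Choice data frame.
#' @export
read_bws_choices <- function(path) {
  read_csv_checked(path, c("respondent_id", "set_id", "best_id", "worst_id"),
                   "BWS choice")
}

#' Load a complete study dataset
#'
#' Reads and cross-validates the four study artefacts against a hierarchy;
#' the result round-trips losslessly with [generate_study()].
#'
#' @param paths Named character vector or list with elements `judgments`,
#'   `bws_design`, `bws_choices`, `cards` (any subset; missing artefacts
#'   are `NULL` in the result).
#' @param hierarchy A [criteria_hierarchy()].
#' @param strict Passed to [read_judgments()].
#' @return Object of class `study_dataset`: list with the four data frames,
#'   the hierarchy, and `provenance` (file paths).
#' @export
read_study_data <- function(paths, hierarchy, strict = TRUE) {
  paths <- as.list(paths)
  out <- list(hierarchy = hierarchy,
              judgments = NULL, bws_design = NULL, bws_choices = NULL,
              cards = NULL,
              provenance = paths)
  if (!is.null(paths$judgments)) {
    out$judgments <- read_judgments(paths$judgments, hierarchy, strict = strict)
  }
  if (!is.null(paths$bws_design)) {
    out$bws_design <- read_bws_design(paths$bws_design, hierarchy)
  }
  if (!is.null(paths$bws_choices)) {
    out$bws_choices <- read_bws_choices(paths$bws_choices)
  }
  if (!is.null(paths$cards)) {
    out$cards <- read_cards(paths$cards, hierarchy)
  }
  structure(out, class = "study_dataset")
}

#' Summarize per-respondent weights
#'
#' Median, quartiles (type-7 linear interpolation) and sample SD (n - 1
#' denominator) of each column of a respondent-by-criterion weight matrix —
#' the numbers behind a boxplot display of cohort priorities. A single
#' respondent yields SD 0 with a flag.
#'
#' @param W Numeric matrix, respondents in rows, criteria in columns.
#' @return Data frame `node`, `median`, `q1`, `q3`, `sd`, `n`, `flag`.
#' @export
summarize_weights <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) < 1) stop("need at least one respondent")
  single <- nrow(W) == 1
  out <- data.frame(
    node = colnames(W),
    median = apply(W, 2, stats::median),
    q1 = apply(W, 2, stats::quantile, probs = 0.25, type = 7, names = FALSE),
    q3 = apply(W, 2, stats::quantile, probs = 0.75, type = 7, names = FALSE),
    sd = if (single) 0 else apply(W, 2, stats::sd),
    n = nrow(W),
    flag = if (single) "single_respondent" else "",
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the full scenario battery and write a report bundle
#'
#' Runs every requested AHP aggregation scenario, the BWS count analysis,
#' the card aggregation, the cross-method comparison, the pooled per-block
#' tau-b table between AHP and BWS respondent rankings, and the bootstrap
#' CI / rank-stability analysis, and writes each as a tidy CSV into
#' `dir` together with a plain-text log of thresholds, seeds and inclusion
#' counts.
#'
#' @param dataset A [read_study_data()] result or the list returned by
#'   [simulate_study()] (plus `hierarchy` taken from its config).
#' @param dir Output directory.
#' @param scenarios Data frame with columns `mode`, `central` (defaults to
#'   the six-scenario battery), and optionally `cr_threshold`.
#' @param cr_threshold Default screening threshold for scenarios without
#'   their own.
#' @param boot_B,boot_seed Bootstrap resamples and seed for the CI table
#'   (the statistic is the AIP geometric global weight).
#' @return Invisibly, a list with all computed tables.
#' @export
build_report <- function(dataset, dir,
                         scenarios = NULL,
                         cr_threshold = 0.1,
                         boot_B = 1000, boot_seed = 1L) {
  hierarchy <- if (!is.null(dataset$hierarchy)) dataset$hierarchy
               else dataset$config$hierarchy
  if (is.null(scenarios)) {
    scenarios <- expand.grid(mode = c("AIJ", "AIP"),
                             central = c("geometric", "arithmetic", "median"),
                             stringsAsFactors = FALSE)
  }
  if (is.null(scenarios$cr_threshold)) scenarios$cr_threshold <- cr_threshold
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  log_lines <- c(paste0("prefrank report ", format(Sys.time(), "%Y-%m-%d")),
                 paste0("cr_threshold default: ", cr_threshold),
                 paste0("bootstrap: B = ", boot_B, ", seed = ", boot_seed))

  fits <- list()
  tidy_rows <- list()
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    label <- paste0(sc$mode, "_", sc$central)
    fit <- suppressWarnings(ahp(dataset$judgments, hierarchy,
                                mode = sc$mode, central = sc$central,
                                cr_threshold = sc$cr_threshold))
    fits[[label]] <- fit
    log_lines <- c(log_lines, paste0(
      "scenario ", label, ": included ", length(fit$inclusion$included),
      ", excluded ", length(fit$inclusion$excluded),
      ", incomplete ", length(fit$inclusion$incomplete)))
    rk <- fit$ranking
    tidy_rows[[label]] <- data.frame(
      scenario = label, node = rk$item,
      local_weight = unlist(lapply(names(hierarchy$blocks), function(b) {
        fit$local[[b]][intersect(rk$item, hierarchy$blocks[[b]]$members)]
      }))[rk$item],
      global_weight = rk$weight, rank = rk$rank, stringsAsFactors = FALSE)
  }
  tidy <- do.call(rbind, tidy_rows)
  rownames(tidy) <- NULL
  utils::write.csv(tidy, file.path(dir, "scenario_weights.csv"), row.names = FALSE)

  wide <- stats::reshape(tidy[c("scenario", "node", "rank")],
                         idvar = "node", timevar = "scenario",
                         direction = "wide")
  names(wide) <- sub("^rank\\.", "", names(wide))
  names(wide)[1] <- "item"
  utils::write.csv(wide, file.path(dir, "scenario_ranks.csv"), row.names = FALSE)

  bfit <- NULL
  comparison <- NULL
  tau_tab <- NULL
  if (!is.null(dataset$bws_choices) && !is.null(dataset$bws_design)) {
    bfit <- bws(dataset$bws_choices, dataset$bws_design)
    comparison <- method_comparison(fits[["AIP_geometric"]], bfit,
                                    cards = dataset$cards,
                                    hierarchy = hierarchy)
    utils::write.csv(comparison, file.path(dir, "method_comparison.csv"),
                     row.names = FALSE)
    tau_tab <- ahp_bws_tau(fits[["AIP_geometric"]], dataset$bws_choices,
                           dataset$bws_design)
    utils::write.csv(tau_tab, file.path(dir, "ahp_bws_tau.csv"),
                     row.names = FALSE)
  }

  boot <- ahp_boot(fits[["AIP_geometric"]], B = boot_B, seed = boot_seed)
  ci_tab <- boot$intervals
  ci_tab$B <- boot_B
  ci_tab$seed <- boot_seed
  stab <- rank_stability(boot)
  ci_tab$robust <- ci_tab$node %in% stab$robust
  utils::write.csv(ci_tab, file.path(dir, "bootstrap_ci.csv"), row.names = FALSE)

  incl <- fits[["AIP_geometric"]]$inclusion$included
  ws <- summarize_weights(
    fits[["AIP_geometric"]]$respondent_global[incl, , drop = FALSE])
  utils::write.csv(ws, file.path(dir, "weight_summary.csv"), row.names = FALSE)

  writeLines(log_lines, file.path(dir, "report_log.txt"))
  invisible(list(fits = fits, tidy = tidy, ranks = wide, bws = bfit,
                 comparison = comparison, tau = tau_tab, boot = boot,
                 stability = stab, weight_summary = ws))
}

#' Pooled AHP-vs-BWS tau-b per block
#'
#' For each comparison block, ranks every respondent's AHP local weights
#' and their individual BWS standardized scores, and computes the pooled
#' within-respondent Kendall tau-b between the two rankings (respondents
#' common to both tasks).
#'
#' @param fit An [ahp()] fit.
#' @param choices,design BWS choice and design data frames.
#' @return Data frame `block`, `tau_b`, `p_value`, `n_pairs`.
#' @export
ahp_bws_tau <- function(fit, choices, design) {
  h <- fit$hierarchy
  tal <- bws_tally(choices, design)
  shared <- intersect(rownames(fit$respondent_local[[1]]),
                      names(tal$by_respondent))
  if (!length(shared)) stop("no respondents common to AHP and BWS data")
  x_by <- y_by <- list()
  for (b in names(h$blocks)) {
    members <- h$blocks[[b]]$members
    x_by[[b]] <- lapply(shared, function(r) {
      ranks_of(rank_table(fit$respondent_local[[b]][r, ]))[members]
    })
    y_by[[b]] <- lapply(shared, function(r) {
      cnt <- tal$by_respondent[[r]]
      cnt <- cnt[cnt$item %in% members, ]
      sc <- stats::setNames(cnt$bw / pmax(cnt$r, 1), cnt$item)
      ranks_of(rank_table(sc - min(sc)))[members]
    })
  }
  rank_concordance(x_by, y_by, level = "pooled")
}
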