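# Reading, writing and describing twin-pair datasets.
#
# A dataset is one row per twin pair (or singleton): family id, zygosity-sex
# group (MZM, DZM, MZF, DZF, DOS), cohort label, and the two binary
# phenotypes. In DOS pairs twin 1 is male by convention; optional sex1/sex2
# columns may override the column order on input and are normalized away.

TWIN_GROUPS <- c("MZM", "DZM", "MZF", "DZF", "DOS")

#' Construct and validate a twin-pair dataset
#'
#' @param records Data frame with columns \code{family_id}, \code{group},
#'   \code{cohort}, \code{pheno1}, \code{pheno2}. Phenotypes are 0/1/NA;
#'   at least one phenotype per row must be non-missing. For DOS rows twin 1
#'   is the male co-twin.
#' @return An object of class \code{twin_dataset} (a data frame with a
#'   \code{cohorts} attribute holding the ordered cohort labels).
#' @export
twin_dataset <- function(records) {
  req <- c("family_id", "group", "cohort", "pheno1", "pheno2")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[req]
  records$family_id <- as.character(records$family_id)
  records$group <- as.character(records$group)
  records$cohort <- as.character(records$cohort)
  for (ph in c("pheno1", "pheno2")) {
    v <- records[[ph]]
    if (is.character(v)) v[v %in% c("", "NA")] <- NA
    v <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & !(v %in% c(0, 1))
    bad_raw <- !is.na(records[[ph]]) & is.na(v) &
      !(as.character(records[[ph]]) %in% c("", "NA"))
    if (any(bad) || any(bad_raw)) {
      stop("phenotype values must be 0, 1 or missing", call. = FALSE)
    }
    records[[ph]] <- as.integer(v)
  }
  if (any(!nzchar(records$group)) || any(!nzchar(records$cohort))) {
    stop("group and cohort labels must be non-empty", call. = FALSE)
  }
  unknown <- !(records$group %in% TWIN_GROUPS)
  if (any(unknown)) {
    stop("unknown group label(s): ",
         paste(unique(records$group[unknown]), collapse = ", "),
         call. = FALSE)
  }
  empty <- is.na(records$pheno1) & is.na(records$pheno2)
  if (any(empty)) {
    stop("rows with both phenotypes missing are not allowed", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(records,
            cohorts = unique(records$cohort),
            class = c("twin_dataset", "data.frame"))
}

#' Number of phenotyped individuals in a dataset
#'
#' Complete pairs count twice, singletons once.
#' @param ds A \code{twin_dataset}.
#' @return Integer count.
#' @export
n_individuals <- function(ds) {
  sum(!is.na(ds$pheno1)) + sum(!is.na(ds$pheno2))
}

#' @export
print.twin_dataset <- function(x, ...) {
  cat("Twin-pair dataset:", nrow(x), "records,", n_individuals(x),
      "individuals\n")
  cat("Cohorts:", paste(attr(x, "cohorts"), collapse = ", "), "\n")
  tab <- table(x$group, x$cohort)
  print(tab)
  invisible(x)
}

#' Read a twin-pair dataset from CSV
#'
#' Expects a UTF-8, comma-separated file with a header naming at least
#' \code{family_id}, \code{group}, \code{cohort}, \code{pheno1},
#' \code{pheno2}; missing phenotypes are empty fields or \code{NA}. Rows
#' with an unrecognized group label, or with both phenotypes missing, are
#' excluded and counted (reported via \code{message()} and in the returned
#' attributes). Optional \code{sex1}/\code{sex2} columns override the
#' twin-1-is-male convention for DOS rows: rows coded female-first are
#' swapped into canonical order.
#'
#' @param path Path to the CSV file.
#' @return A \code{twin_dataset}; attributes \code{n_excluded_group} and
#'   \code{n_excluded_missing} record exclusion counts.
#' @export
read_twin_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("family_id", "group", "cohort", "pheno1", "pheno2")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (ph in c("pheno1", "pheno2")) {
    v <- raw[[ph]]
    v[v %in% c("", "NA")] <- NA
    raw[[ph]] <- suppressWarnings(as.numeric(v))
  }
  unknown <- !(raw$group %in% TWIN_GROUPS)
  n_excl_group <- sum(unknown)
  if (n_excl_group) {
    message("read_twin_dataset: excluded ", n_excl_group,
            " row(s) with unknown group label")
    raw <- raw[!unknown, , drop = FALSE]
  }
  empty <- is.na(raw$pheno1) & is.na(raw$pheno2)
  n_excl_missing <- sum(empty)
  if (n_excl_missing) {
    warning("excluded ", n_excl_missing,
            " row(s) with both phenotypes missing", call. = FALSE)
    raw <- raw[!empty, , drop = FALSE]
  }
  # normalize DOS rows to twin 1 = male when sex columns are present
  if (all(c("sex1", "sex2") %in% names(raw))) {
    swap <- raw$group == "DOS" & raw$sex1 == "F"
    if (any(swap)) {
      tmp <- raw$pheno1[swap]
      raw$pheno1[swap] <- raw$pheno2[swap]
      raw$pheno2[swap] <- tmp
    }
  }
  ds <- twin_dataset(raw[req])
  attr(ds, "n_excluded_group") <- n_excl_group
  attr(ds, "n_excluded_missing") <- n_excl_missing
  ds
}

#' Write a twin-pair dataset to CSV
#'
#' Writes the canonical five columns plus \code{sex1}/\code{sex2} (derived
#' from group and the twin-1-is-male DOS convention), with missing
#' phenotypes as empty fields, so the file round-trips through
#' \code{\link{read_twin_dataset}}.
#'
#' @param ds A \code{twin_dataset}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_twin_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "twin_dataset"))
  out <- as.data.frame(ds)
  sexes <- .group_sexes(out$group)
  out$sex1 <- sexes$sex1
  out$sex2 <- sexes$sex2
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# per-record sexes of twin 1 / twin 2 given the group label
.group_sexes <- function(group) {
  sex1 <- ifelse(group %in% c("MZM", "DZM", "DOS"), "M", "F")
  sex2 <- ifelse(group %in% c("MZM", "DZM"), "M",
                 ifelse(group == "DOS", "F", "F"))
  list(sex1 = sex1, sex2 = sex2)
}

# Round half away from zero to `digits` decimals (printed-table convention).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Prevalence table by sex, zygosity class and cohort
#'
#' Tallies every non-missing individual phenotype once into sex (M/F) by
#' zygosity-class (MZ, same-sex DZ, opposite-sex DZ) by cohort cells, plus a
#' per-sex Total row. Opposite-sex DZ individuals are tallied under their
#' own sex (twin 1 male, twin 2 female). Percentages use round-half-up to
#' one decimal.
#'
#' @param ds A non-empty \code{twin_dataset}.
#' @return Data frame with columns \code{cohort}, \code{sex},
#'   \code{zygosity_class} (\code{MZ}, \code{DZss}, \code{DZos},
#'   \code{Total}), \code{n_total}, \code{n_ever}, \code{pct}.
#' @export
prevalence_table <- function(ds) {
  stopifnot(inherits(ds, "twin_dataset"))
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  long <- .individual_long(ds)
  cls <- ifelse(long$group %in% c("MZM", "MZF"), "MZ",
                ifelse(long$group == "DOS", "DZos", "DZss"))
  cells <- aggregate(cbind(n_total = !is.na(long$pheno),
                           n_ever = long$pheno %in% 1),
                     by = list(cohort = long$cohort, sex = long$sex,
                               zygosity_class = cls),
                     FUN = sum)
  tot <- aggregate(cells[c("n_total", "n_ever")],
                   by = cells[c("cohort", "sex")], FUN = sum)
  tot$zygosity_class <- "Total"
  out <- rbind(cells, tot[names(cells)])
  out$pct <- round_half_up(100 * out$n_ever / out$n_total, 1)
  ord <- order(out$cohort, out$sex,
               match(out$zygosity_class, c("MZ", "DZss", "DZos", "Total")))
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("prevalence_table", "data.frame")
  out
}

# one row per phenotyped individual: cohort, group, sex, pheno
.individual_long <- function(ds) {
  sexes <- .group_sexes(ds$group)
  t1 <- data.frame(cohort = ds$cohort, group = ds$group, sex = sexes$sex1,
                   pheno = ds$pheno1, stringsAsFactors = FALSE)
  t2 <- data.frame(cohort = ds$cohort, group = ds$group, sex = sexes$sex2,
                   pheno = ds$pheno2, stringsAsFactors = FALSE)
  long <- rbind(t1, t2)
  long[!is.na(long$pheno), , drop = FALSE]
}

#' Two-group prevalence comparison (Pearson and threshold-equality LRT)
#'
#' Compares the proportion ever affected between two strata of individuals:
#' either the two cohorts (within a sex, optionally within a zygosity
#' class), or MZ versus DZ (same- plus opposite-sex pooled) within a sex and
#' cohort. Two tests are reported and neither is privileged: the Pearson
#' chi-square on the 2x2 individual-level table (no continuity correction)
#' and the likelihood-ratio test of threshold equality. Because a liability
#' threshold is a one-to-one function of a prevalence, the latter equals the
#' binomial deviance G-test of two free proportions versus one pooled.
#'
#' @param ds A \code{twin_dataset}.
#' @param factor \code{"cohort"} or \code{"zygosity"}.
#' @param sex \code{"M"} or \code{"F"}.
#' @param cohort Cohort label (required when \code{factor = "zygosity"}).
#' @param zygosity_class Optional restriction to \code{"MZ"}, \code{"DZss"}
#'   or \code{"DZos"} when comparing cohorts.
#' @return List with the two 2x2 margins and \code{chisq}, \code{p_pearson},
#'   \code{lrt}, \code{p_lrt} (both tests on 1 df).
#' @export
compare_prevalence <- function(ds, factor = c("cohort", "zygosity"),
                               sex, cohort = NULL, zygosity_class = NULL) {
  factor <- match.arg(factor)
  long <- .individual_long(ds)
  long <- long[long$sex == sex, , drop = FALSE]
  if (factor == "cohort") {
    if (!is.null(zygosity_class)) {
      cls <- ifelse(long$group %in% c("MZM", "MZF"), "MZ",
                    ifelse(long$group == "DOS", "DZos", "DZss"))
      long <- long[cls == zygosity_class, , drop = FALSE]
    }
    levels_ <- attr(ds, "cohorts")
    grp <- long$cohort
  } else {
    if (is.null(cohort)) stop("'cohort' is required for factor = \"zygosity\"")
    long <- long[long$cohort == cohort, , drop = FALSE]
    grp <- ifelse(long$group %in% c("MZM", "MZF"), "MZ", "DZ")
    levels_ <- c("MZ", "DZ")
  }
  ever <- tapply(long$pheno, factor(grp, levels = levels_), sum)
  tot <- tapply(long$pheno, factor(grp, levels = levels_), length)
  if (length(ever) != 2 || any(is.na(tot)) || any(tot == 0)) {
    stop("comparison requires two strata with positive denominators",
         call. = FALSE)
  }
  prevalence_test(ever, tot, names = names(tot))
}

#' Compare two proportions from counts
#'
#' Workhorse behind \code{\link{compare_prevalence}}; usable directly on
#' printed counts. See that function for the two tests reported.
#'
#' @param ever Length-2 vector of affected counts.
#' @param total Length-2 vector of totals (positive).
#' @param names Optional stratum labels.
#' @return List with \code{chisq}, \code{df}, \code{p_pearson}, \code{lrt},
#'   \code{p_lrt}, \code{prop}.
#' @export
prevalence_test <- function(ever, total, names = NULL) {
  stopifnot(length(ever) == 2, length(total) == 2, all(total > 0),
            all(ever >= 0), all(ever <= total))
  tab <- cbind(ever = ever, not = total - ever)
  if (ever[1] * total[2] == ever[2] * total[1]) {
    chisq <- 0; p_pearson <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chisq <- unname(ct$statistic); p_pearson <- ct$p.value
  }
  # threshold-equality LRT = binomial deviance G-test, 1 df
  p_pool <- sum(ever) / sum(total)
  ll <- function(k, n, p) {
    ifelse(k > 0, k * log(p), 0) + ifelse(n - k > 0, (n - k) * log(1 - p), 0)
  }
  p_sep <- ever / total
  g <- 2 * (sum(ll(ever, total, pmin(pmax(p_sep, 1e-12), 1 - 1e-12))) -
              sum(ll(ever, total, p_pool)))
  g <- max(g, 0)
  list(strata = names, prop = p_sep, chisq = chisq, df = 1L,
       p_pearson = p_pearson, lrt = g,
       p_lrt = stats::pchisq(g, df = 1, lower.tail = FALSE))
}

#' Write a prevalence table as CSV and aligned text
#'
#' @param tab A \code{prevalence_table}.
#' @param csv_path,txt_path Output paths (either may be NULL to skip).
#' @return Invisibly, the formatted text lines.
#' @export
write_prevalence_table <- function(tab, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  fmt <- sprintf("%-10s %-3s %-6s %6d %6d %6.1f%%",
                 tab$cohort, tab$sex, tab$zygosity_class,
                 tab$n_total, tab$n_ever, tab$pct)
  lines <- c(sprintf("%-10s %-3s %-6s %6s %6s %7s",
                     "cohort", "sex", "class", "N", "Never", "%ever"), fmt)
  if (!is.null(txt_path)) writeLines(lines, txt_path)
  invisible(lines)
}
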