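#' Load the packaged per-dog induction outcome fixture
#'
#' Returns the study's per-dog induction records: for each dog, four
#' programmed-stimulation inductions (the first two pre-drug under saline,
#' the last two after treatment) each with an episode type (`VT`, `VF`,
#' `VT_ns`, `NI` not inducible, `nd` not done) and a set of mechanism
#' labels (`EFo` endocardial focal, `EpFo` epicardial focal, `R`
#' epicardial reentry, `RE` endocardial reentry). Group sizes are APO 10,
#' OXY 9, BOTH 8, CONTROL 27.
#'
#' @param group one of `"APO"`, `"OXY"`, `"BOTH"`, `"CONTROL"`, or
#'   `"all"` for every record.
#' @param path optional path to an induction CSV in the packaged format
#'   (columns dog_id, group, induction_index, episode_type, mechanisms,
#'   sustained_flag); defaults to the packaged fixture.
#' @return list of `induction_record` objects, each a list with `dog_id`,
#'   `group`, and `inductions` (list of `list(type, mechanisms)` in
#'   induction order).
#' @export
load_study_fixture <- function(group = c("APO", "OXY", "BOTH", "CONTROL", "all"),
                               path = NULL) {
  group <- match.arg(group)
  if (is.null(path))
    path <- system.file("extdata", "induction_records.csv", package = "vtmap3d",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = character())
  if (group != "all") tab <- tab[tab$group == group, , drop = FALSE]
  if (!nrow(tab)) stop("unknown or empty group: ", group)
  tab$episode_type <- sub("-", "_", tab$episode_type)
  bad <- setdiff(unique(tab$episode_type), c("VT", "VF", "VT_ns", "NI", "nd"))
  if (length(bad)) stop("unknown episode type(s): ", paste(bad, collapse = ", "))
  recs <- lapply(split(tab, factor(tab$dog_id, levels = unique(tab$dog_id))), function(d) {
    d <- d[order(d$induction_index), , drop = FALSE]
    ind <- lapply(seq_len(nrow(d)), function(i) {
      mech <- d$mechanisms[i]
      mech <- if (is.na(mech) || mech == "") character(0) else strsplit(mech, ";", fixed = TRUE)[[1L]]
      bad <- setdiff(mech, c("EFo", "EpFo", "R", "RE"))
      if (length(bad)) stop("unknown mechanism label(s): ", paste(bad, collapse = ", "))
      list(type = d$episode_type[i], mechanisms = mech)
    })
    structure(list(dog_id = d$dog_id[1L], group = d$group[1L], inductions = ind),
              class = "induction_record")
  })
  unname(recs)
}

mech_category <- function(labels) {
  out <- character(0)
  if (any(labels %in% c("EFo", "EpFo"))) out <- c(out, "focal")
  if (any(labels %in% c("R", "RE"))) out <- c(out, "reentry")
  out
}

#' Mechanism categories reproducibly induced pre-drug
#'
#' A mechanism category (focal = EFo/EpFo, reentry = R/RE) is
#' reproducible when it appears in the sustained episode of both
#' pre-drug inductions (I and II). Reproducibility is assessed at the
#' category level, not the exact label: an epicardial reentry at I
#' followed by an endocardial reentry at II still counts as reproducible
#' reentry.
#'
#' @param record an `induction_record`.
#' @return character subset of `c("focal", "reentry")`.
#' @export
reproducible_categories <- function(record) {
  stopifnot(inherits(record, "induction_record"))
  ind <- record$inductions
  if (length(ind) < 2L) return(character(0))
  sustained_mechs <- function(x) if (x$type %in% c("VT", "VF")) x$mechanisms else character(0)
  intersect(mech_category(sustained_mechs(ind[[1L]])),
            mech_category(sustained_mechs(ind[[2L]])))
}

#' Mechanism categories blocked by the intervention
#'
#' A reproducible category is blocked when the final completed
#' post-treatment induction (the last of III/IV that was actually done)
#' contains no sustained episode with a mechanism of that category. Not
#' inducible (`NI`), truncated series (`nd` at IV with the block read at
#' III), and non-sustained VT (`VT_ns`, which terminates on its own in
#' under 10 s) all count as absence of the mechanism.
#'
#' @param record an `induction_record`.
#' @return character subset of `c("focal", "reentry")`; attribute
#'   `"indeterminate"` is `TRUE` when no post-treatment induction was
#'   completed.
#' @export
blocked_categories <- function(record) {
  stopifnot(inherits(record, "induction_record"))
  repro <- reproducible_categories(record)
  post <- record$inductions[-(1:2)]
  post <- Filter(function(x) x$type != "nd", post)
  if (!length(post)) {
    out <- character(0)
    attr(out, "indeterminate") <- TRUE
    return(out)
  }
  final <- post[[length(post)]]
  present <- if (final$type %in% c("VT", "VF")) mech_category(final$mechanisms) else character(0)
  setdiff(repro, present)
}

#' Tally induction block for one treatment group
#'
#' Counts, over a group's records, the experiments with the focal
#' category blocked, the reentry category blocked, and at least one
#' category blocked (the headline "Total" row of the study summary).
#'
#' @param records list of `induction_record`s from one group.
#' @return list with `group`, `n`, `focal_blocked`, `reentry_blocked`,
#'   `total_blocked`.
#' @export
summarize_group <- function(records) {
  if (!length(records)) stop("empty group")
  grp <- unique(vapply(records, `[[`, "", "group"))
  if (length(grp) != 1L) stop("records from mixed groups")
  bl <- lapply(records, blocked_categories)
  list(group = grp, n = length(records),
       focal_blocked = sum(vapply(bl, function(b) "focal" %in% b, logical(1))),
       reentry_blocked = sum(vapply(bl, function(b) "reentry" %in% b, logical(1))),
       total_blocked = sum(lengths(bl) > 0L))
}

#' Reconstruct the study's group-level block table
#'
#' Applies [reproducible_categories()] / [blocked_categories()] to all
#' four packaged groups and returns the focal / reentry / total block
#' counts per group.
#'
#' @param path optional fixture path, see [load_study_fixture()].
#' @return data.frame with columns `group`, `n`, `focal_blocked`,
#'   `reentry_blocked`, `total_blocked`.
#' @export
summarize_study <- function(path = NULL) {
  groups <- c("APO", "OXY", "BOTH", "CONTROL")
  do.call(rbind, lapply(groups, function(g) {
    s <- summarize_group(load_study_fixture(g, path = path))
    data.frame(group = s$group, n = s$n, focal_blocked = s$focal_blocked,
               reentry_blocked = s$reentry_blocked, total_blocked = s$total_blocked,
               stringsAsFactors = FALSE)
  }))
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Computes the Pearson statistic N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
#' with 1 degree of freedom, optionally with the Yates continuity
#' correction. Used for treated-vs-control induction-block comparisons.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of nonnegative
#'   counts.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df` (= 1).
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  m <- as_2x2(table)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) stop("undefined-test: zero margin")
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value with both margins fixed: the sum of
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (a small relative tolerance guards against floating-point
#' ties, as is conventional).
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of nonnegative
#'   integer counts.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_two_tailed <- function(table) {
  m <- as_2x2(table)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; k <- a + c_; n <- a + b + c_ + d
  lo <- max(0L, k - (n - r1)); hi <- min(r1, k)
  x <- lo:hi
  p <- stats::dhyper(x, r1, n - r1, k)
  p_obs <- p[x == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

as_2x2 <- function(table) {
  m <- if (is.matrix(table)) table else matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (!all(dim(m) == c(2L, 2L))) stop("table must be 2x2")
  if (any(m < 0) || any(!is.finite(m))) stop("counts must be finite and nonnegative")
  m
}

#' Proarrhythmia tally helper
#'
#' Simple descriptive count for a series of previously non-inducible
#' animals challenged after drug: how many developed any sustained
#' VT/VF. No statistics are attached.
#'
#' @param outcomes character vector of episode types observed after drug
#'   (`"VT"`, `"VF"`, `"VT_ns"`, `"NI"`).
#' @return list with `n` and `induced`.
#' @export
proarrhythmia_tally <- function(outcomes) {
  list(n = length(outcomes), induced = sum(outcomes %in% c("VT", "VF")))
}
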