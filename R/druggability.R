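# Rule-based druggability matching: somatic alterations are matched against
# a transparent, versioned rules table mapping gene + alteration pattern to
# drug, predicted effect (response/resistance) and evidence level. No
# network service is consulted.

RULE_PATTERNS <- c("exact_aa", "truncating", "frameshift",
                   "any_nonsynonymous", "position_class")
RULE_EFFECTS <- c("responsive", "resistant")
EVIDENCE_LEVELS <- c("FDA", "NCCN", "late_trials", "early_trials",
                     "case_report", "pre_clinical")
TRUNCATING_EFFECTS <- c("nonsense", "frameshift_ins", "frameshift_del")
FRAMESHIFT_EFFECTS <- c("frameshift_ins", "frameshift_del")

#' Validate a druggability rules table
#'
#' Schema: `gene`, `pattern_kind` (one of exact_aa, truncating, frameshift,
#' any_nonsynonymous, position_class), `pattern_payload` (an amino-acid
#' change for exact_aa, a `start-end` residue range for position_class,
#' empty otherwise), `drug`, `effect` (responsive/resistant), `evidence`
#' (FDA, NCCN, late_trials, early_trials, case_report, pre_clinical),
#' `disease`.
#'
#' @param rules data.frame.
#' @return the validated rules, with `evidence` ordered as a factor.
#' @export
validate_rules <- function(rules) {
  required <- TABLE_SCHEMAS$rules
  missing <- setdiff(required, names(rules))
  if (length(missing)) {
    stop("rules table is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_row <- function(i, why) stop("malformed rule in row ", i, ": ", why)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (is.na(r$gene) || r$gene == "") bad_row(i, "empty gene")
    if (!r$pattern_kind %in% RULE_PATTERNS) {
      bad_row(i, paste0("unknown pattern_kind '", r$pattern_kind, "'"))
    }
    if (!r$effect %in% RULE_EFFECTS) {
      bad_row(i, paste0("unknown effect '", r$effect, "'"))
    }
    if (!r$evidence %in% EVIDENCE_LEVELS) {
      bad_row(i, paste0("unknown evidence '", r$evidence, "'"))
    }
    if (r$pattern_kind == "exact_aa" &&
        (is.na(r$pattern_payload) || r$pattern_payload == "")) {
      bad_row(i, "exact_aa requires an amino-acid payload")
    }
    if (r$pattern_kind == "position_class" &&
        (is.na(r$pattern_payload) ||
         !grepl("^[0-9]+-[0-9]+$", r$pattern_payload))) {
      bad_row(i, "position_class requires a 'start-end' payload")
    }
  }
  class(rules) <- unique(c("druggability_rules", class(rules)))
  rules
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# strip a leading "p." and uppercase, so "p.G12D" == "G12D"
normalize_aa <- function(x) toupper(sub("^p\\.", "", x))

# first residue number embedded in an amino-acid label, NA if none
aa_position <- function(x) {
  m <- regmatches(x, regexpr("[0-9]+", x))
  out <- rep(NA_integer_, length(x))
  out[lengths(regmatches(x, gregexpr("[0-9]+", x))) > 0] <-
    suppressWarnings(as.integer(m))
  out
}

rule_matches_call <- function(rule, calls) {
  hit <- !is.na(calls$gene) & calls$gene == rule$gene
  if (!any(hit)) return(hit)
  switch(rule$pattern_kind,
         exact_aa = hit & !is.na(calls$aa_change) &
           normalize_aa(calls$aa_change) == normalize_aa(rule$pattern_payload),
         truncating = hit & calls$effect %in% TRUNCATING_EFFECTS,
         frameshift = hit & calls$effect %in% FRAMESHIFT_EFFECTS,
         any_nonsynonymous = hit & calls$effect != "synonymous",
         position_class = {
           range <- as.integer(strsplit(rule$pattern_payload, "-",
                                        fixed = TRUE)[[1]])
           pos <- aa_position(calls$aa_change)
           hit & !is.na(pos) & pos >= range[1] & pos <= range[2]
         })
}

#' Match somatic alterations against druggability rules
#'
#' A call matches a rule iff the gene is equal and the rule's pattern is
#' satisfied (`exact_aa`: normalized amino-acid equality; `truncating`:
#' nonsense or frameshift consequence; `frameshift`: frameshift
#' consequence; `any_nonsynonymous`: any consequence other than synonymous;
#' `position_class`: affected residue inside the payload range). A variant
#' may match several rules and every match is reported, sorted by evidence
#' level (FDA first, pre-clinical last). Output is independent of call and
#' rule order.
#'
#' @param calls prioritized somatic [variant_calls()].
#' @param rules a [validate_rules()]-validated table (default the bundled
#'   [fixture_rules()]).
#' @return list of class `actionability_report`: `matches` (one row per
#'   call-rule match), `patients` (per-sample `n_matches` and
#'   `has_druggable`).
#' @export
match_rules <- function(calls, rules = fixture_rules()) {
  rules <- validate_rules(as.data.frame(rules))
  match_rows <- lapply(seq_len(nrow(rules)), function(i) {
    hit <- rule_matches_call(rules[i, ], calls)
    if (!any(hit)) return(NULL)
    h <- calls[hit, , drop = FALSE]
    data.frame(sample_id = h$sample_id, gene = h$gene,
               aa_change = h$aa_change, chrom = h$chrom, pos = h$pos,
               ref = h$ref, alt = h$alt,
               drug = rules$drug[i], effect = rules$effect[i],
               evidence = rules$evidence[i], disease = rules$disease[i],
               pattern_kind = rules$pattern_kind[i],
               stringsAsFactors = FALSE)
  })
  match_rows <- match_rows[!vapply(match_rows, is.null, logical(1))]
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(sample_id = character(), gene = character(),
               aa_change = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), drug = character(),
               effect = character(), evidence = character(),
               disease = character(), pattern_kind = character(),
               stringsAsFactors = FALSE)
  ord <- order(match(matches$evidence, EVIDENCE_LEVELS), matches$sample_id,
               matches$gene, matches$pos, matches$drug)
  matches <- matches[ord, , drop = FALSE]
  rownames(matches) <- NULL

  all_samples <- sort(unique(calls$sample_id))
  n_matches <- vapply(all_samples, function(s) {
    sum(matches$sample_id == s)
  }, integer(1))
  patients <- data.frame(sample_id = all_samples,
                         n_matches = unname(n_matches),
                         has_druggable = unname(n_matches) > 0L,
                         stringsAsFactors = FALSE)
  structure(list(matches = matches, patients = patients),
            class = "actionability_report")
}

#' Cohort actionability summary
#'
#' @param report an [match_rules()] report.
#' @param n_samples cohort size (the denominator; samples with zero
#'   surviving calls never appear in the report but still count here).
#' @return list: `fraction_actionable` (samples with >= 1 match over
#'   `n_samples`), `n_actionable`, `match_count_range` (min/max per-patient
#'   match count among patients with calls), and `per_rule` (carrier count
#'   per drug/effect/evidence rule).
#' @export
summarize_actionability <- function(report, n_samples) {
  stopifnot(inherits(report, "actionability_report"), n_samples >= 1)
  n_act <- sum(report$patients$has_druggable)
  per_rule <- if (nrow(report$matches)) {
    agg <- aggregate(sample_id ~ drug + effect + evidence,
                     data = report$matches,
                     FUN = function(s) length(unique(s)))
    names(agg)[names(agg) == "sample_id"] <- "carriers"
    agg[order(match(agg$evidence, EVIDENCE_LEVELS), -agg$carriers, agg$drug), ,
        drop = FALSE]
  } else {
    data.frame(drug = character(), effect = character(),
               evidence = character(), carriers = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(per_rule) <- NULL
  list(fraction_actionable = n_act / n_samples,
       n_actionable = n_act,
       match_count_range = if (nrow(report$patients))
         range(report$patients$n_matches) else c(NA_integer_, NA_integer_),
       per_rule = per_rule)
}
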