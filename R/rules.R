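# Declarative ADL rules. A rule carries a target label, a compartment
# scope, duration bounds, a conjunctive predicate list over features of a
# candidate window's ambient value matrix, an optional prior-fact
# requirement (e.g. "a sleeping event starts shortly after this window"),
# and a unique priority used for conflict resolution (smaller = stronger).

RULE_FEATURES <- c(
  "duration_s", "motion_density",
  "delta_temperature", "delta_humidity",
  "abs_delta_temperature", "abs_delta_humidity",
  "range_luminance", "mean_luminance",
  "n_transients", "tod_start", "tod_mid"
)
RULE_OPS <- c("<", "<=", ">", ">=", "==", "!=", "in_range")
FACT_RELATIONS <- c("starts_within_after", "ends_within_before")

#' Construct a single classification rule
#'
#' @param id Short unique identifier.
#' @param target ADL label the rule asserts.
#' @param compartment Compartment scope (room name, or `"any"`).
#' @param priority Unique integer; smaller numbers win conflict
#'   resolution.
#' @param duration_min_s,duration_max_s Window duration bounds (s).
#' @param predicates List of `list(feature, op, value)` conditions, all of
#'   which must hold. `op` is one of `<, <=, >, >=, ==, !=, in_range`
#'   (for `in_range`, `value` is `c(lo, hi)`; `lo > hi` wraps midnight for
#'   time-of-day features).
#' @param requires_fact Optional prior-fact requirement:
#'   `list(label, relation, lag_s)` with relation
#'   `"starts_within_after"` (a fact of that label starts within `lag_s`
#'   after the window ends) or `"ends_within_before"` (a fact ends within
#'   `lag_s` before the window starts).
#' @return A `list` of class `adl_rule`.
#' @export
rule <- function(id, target, compartment, priority,
                 duration_min_s, duration_max_s,
                 predicates, requires_fact = NULL) {
  predicates <- lapply(predicates, function(p) {
    list(feature = p$feature, op = p$op, value = as.numeric(p$value))
  })
  if (!is.null(requires_fact)) {
    requires_fact <- list(
      label = requires_fact$label, relation = requires_fact$relation,
      lag_s = as.numeric(requires_fact$lag_s)
    )
  }
  structure(
    list(
      id = id, target = target, compartment = compartment,
      priority = as.integer(priority),
      duration_min_s = as.numeric(duration_min_s),
      duration_max_s = as.numeric(duration_max_s),
      predicates = predicates, requires_fact = requires_fact
    ),
    class = "adl_rule"
  )
}

#' Assemble rules into a validated repository
#'
#' Validation enforces the repository invariants: unique rule ids and
#' priorities, known target labels, known feature names and comparators,
#' non-empty predicate lists and `duration_min_s <= duration_max_s`.
#' Rules are stored in priority order (the parsed look-up form used by the
#' inference engine).
#'
#' @param rules List of [rule()] objects.
#' @return An object of class `rule_repository`.
#' @export
rule_repository <- function(rules) {
  for (r in rules) {
    bad <- function(why) {
      stop_adlsense("invalid rule '", r$id, "': ", why,
        class = "adlsense_schema_error"
      )
    }
    if (!is_adl_label(r$target)) bad(paste0("unknown target label ", r$target))
    if (r$duration_min_s > r$duration_max_s) bad("duration min > max")
    if (length(r$predicates) == 0) bad("empty predicate list")
    for (p in r$predicates) {
      if (!p$feature %in% RULE_FEATURES) bad(paste0("unknown feature ", p$feature))
      if (!p$op %in% RULE_OPS) bad(paste0("unknown comparator ", p$op))
      if (p$op == "in_range" && length(p$value) != 2) bad("in_range needs c(lo, hi)")
    }
    if (!is.null(r$requires_fact)) {
      if (!is_adl_label(r$requires_fact$label)) bad("unknown fact label")
      if (!r$requires_fact$relation %in% FACT_RELATIONS) bad("unknown fact relation")
      if (r$requires_fact$lag_s < 0) bad("negative fact lag")
    }
  }
  prios <- vapply(rules, function(r) r$priority, integer(1))
  if (anyDuplicated(prios)) {
    stop_adlsense(
      "duplicate rule priority: ",
      paste(unique(prios[duplicated(prios)]), collapse = ", "),
      class = "adlsense_schema_error"
    )
  }
  ids <- vapply(rules, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop_adlsense("duplicate rule id: ", ids[duplicated(ids)][1],
      class = "adlsense_schema_error"
    )
  }
  structure(list(rules = rules[order(prios)]), class = "rule_repository")
}

#' @export
print.rule_repository <- function(x, ...) {
  cat("<rule_repository>", length(x$rules), "rules\n")
  for (r in x$rules) {
    cat(sprintf(
      "  [%2d] %-22s -> %-22s (%s, %g-%g s, %d predicates%s)\n",
      r$priority, r$id, r$target, paste(r$compartment, collapse = "|"),
      r$duration_min_s, r$duration_max_s, length(r$predicates),
      if (is.null(r$requires_fact)) "" else paste0(", needs ", r$requires_fact$label)
    ))
  }
  invisible(x)
}

#' @export
length.rule_repository <- function(x) length(x$rules)

#' The shipped default rulebase
#'
#' Thresholds are calibrated against the default [emission_model()]:
#' toileting needs a lit bathroom, a flush-handle transient and stable
#' humidity/temperature; grooming is recognised by the shower humidity
#' rise; cooking by a fridge-door transient plus a kitchen temperature
#' rise; eating by a quiet kitchen presence after a cooking fact (or a
#' longer standalone sitting, covering delivered food); watching TV by the
#' TV luminance signature during evening hours with low motion; seated
#' activity is the lit daytime living-room fallback; sleeping is a long,
#' dark, low-motion bedroom presence; getting ready for bed is a short lit
#' bathroom visit just before a sleeping fact (a two-pass inference).
#'
#' @return A `rule_repository`.
#' @export
default_rules <- function() {
  rule_repository(list(
    rule("sleeping", "sleeping", "bedroom", 1, 3600, 43200,
      predicates = list(
        list(feature = "mean_luminance", op = "<=", value = 25),
        list(feature = "motion_density", op = "<=", value = 0.35)
      )
    ),
    rule("grooming_shower", "grooming", "bathroom", 2, 600, 3600,
      predicates = list(
        list(feature = "delta_humidity", op = ">=", value = 3)
      )
    ),
    rule("getting_ready_for_bed", "getting_ready_for_bed", "bathroom", 3, 120, 1200,
      predicates = list(
        list(feature = "mean_luminance", op = ">=", value = 25)
      ),
      requires_fact = list(label = "sleeping", relation = "starts_within_after", lag_s = 1800)
    ),
    rule("toileting", "toileting", "bathroom", 4, 120, 900,
      predicates = list(
        list(feature = "n_transients", op = ">=", value = 1),
        list(feature = "abs_delta_humidity", op = "<", value = 2),
        list(feature = "abs_delta_temperature", op = "<", value = 1),
        list(feature = "mean_luminance", op = ">=", value = 25)
      )
    ),
    rule("cooking", "cooking", "kitchen", 5, 600, 5400,
      predicates = list(
        list(feature = "n_transients", op = ">=", value = 1),
        list(feature = "delta_temperature", op = ">=", value = 0.5)
      )
    ),
    rule("eating_after_cooking", "eating", "kitchen", 6, 600, 3600,
      predicates = list(
        list(feature = "n_transients", op = "==", value = 0),
        list(feature = "motion_density", op = "<=", value = 0.95)
      ),
      requires_fact = list(label = "cooking", relation = "ends_within_before", lag_s = 2700)
    ),
    rule("watching_tv", "watching_tv", "living_room", 7, 1200, 14400,
      predicates = list(
        list(feature = "mean_luminance", op = "in_range", value = c(25, 90)),
        list(feature = "tod_mid", op = "in_range", value = c(66600, 86100)),
        list(feature = "motion_density", op = "<=", value = 0.6)
      )
    ),
    rule("seated_activity", "seated_activity", "living_room", 8, 1200, 14400,
      predicates = list(
        list(feature = "tod_mid", op = "in_range", value = c(25200, 68400)),
        list(feature = "mean_luminance", op = ">", value = 90),
        list(feature = "motion_density", op = "<=", value = 0.95)
      )
    ),
    rule("eating_standalone", "eating", "kitchen", 9, 900, 3600,
      predicates = list(
        list(feature = "n_transients", op = "==", value = 0),
        list(feature = "abs_delta_temperature", op = "<", value = 0.5),
        list(feature = "motion_density", op = "<=", value = 0.95)
      )
    ),
    rule("grooming_dry", "grooming", "bathroom", 10, 1080, 3600,
      predicates = list(
        list(feature = "mean_luminance", op = ">=", value = 25),
        list(feature = "abs_delta_humidity", op = "<", value = 3)
      )
    )
  ))
}

# ---------------------------------------------------------------------------
# JSON round trip
# ---------------------------------------------------------------------------

rule_to_list <- function(r) {
  out <- list(
    id = r$id, target = r$target, compartment = r$compartment,
    priority = r$priority,
    duration_min_s = r$duration_min_s, duration_max_s = r$duration_max_s,
    predicates = lapply(r$predicates, function(p) {
      list(feature = p$feature, op = p$op, value = p$value)
    })
  )
  if (!is.null(r$requires_fact)) out$requires_fact <- r$requires_fact
  out
}

#' Read or write a rule repository as JSON
#'
#' `parse_rules()` translates the declarative rule file into the validated
#' in-memory look-up form used by the inference engine; it accepts a file
#' path or a JSON string. The round trip
#' `parse_rules(write_rules(repo))` reproduces the repository.
#'
#' @param x File path or JSON string.
#' @param repo A `rule_repository`.
#' @param path Output file path.
#' @return `parse_rules()` returns a `rule_repository`.
#' @export
parse_rules <- function(x) {
  parsed <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (is.null(parsed$rules)) {
    stop_adlsense("rule file has no 'rules' member", class = "adlsense_schema_error")
  }
  rules <- lapply(parsed$rules, function(r) {
    req <- c("id", "target", "compartment", "priority", "duration_min_s", "duration_max_s", "predicates")
    miss <- setdiff(req, names(r))
    if (length(miss)) {
      stop_adlsense("rule '", r$id %||% "?", "' lacks fields: ", paste(miss, collapse = ", "),
        class = "adlsense_schema_error"
      )
    }
    rule(
      id = r$id, target = r$target,
      compartment = unlist(r$compartment),
      priority = r$priority,
      duration_min_s = r$duration_min_s, duration_max_s = r$duration_max_s,
      predicates = lapply(r$predicates, function(p) {
        list(feature = p$feature, op = p$op, value = unlist(p$value))
      }),
      requires_fact = if (is.null(r$requires_fact)) {
        NULL
      } else {
        list(
          label = r$requires_fact$label,
          relation = r$requires_fact$relation,
          lag_s = r$requires_fact$lag_s
        )
      }
    )
  })
  rule_repository(rules)
}

#' @rdname parse_rules
#' @export
write_rules <- function(repo, path) {
  stopifnot(inherits(repo, "rule_repository"))
  jsonlite::write_json(
    list(rules = lapply(repo$rules, rule_to_list)),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
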