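# The detection-rule language. A rule names a product category, two
# distances (cutoff between core genes, neighbourhood flanking the core,
# both written in kb) and a boolean condition over profile hits, with an
# optional EXTENDS condition that absorbs additional core genes:
#
#   RULE trans-AT-PKS CATEGORY transAT-PKS CUTOFF 20 NEIGHBOURHOOD 20
#     CONDITIONS PKS_KS and PKS_AT
#     EXTENDS PKS_KS
#
# Condition expressions support and / or / not (precedence: not > and >
# or), parentheses, bare profile names, minimum(n, [p1, p2, ...]) and
# minscore(profile, bits).

# ---- condition node constructors -------------------------------------------

#' Condition-tree constructors
#'
#' Build rule condition trees programmatically; [parse_rules()] produces
#' the same structures from DSL text.
#'
#' @param ... Child condition nodes (`cond_and`, `cond_or`).
#' @param x A child node (`cond_not`).
#' @param profile_name A profile name.
#' @param count Minimum number of distinct profiles that must hit.
#' @param profiles Character vector of profile names.
#' @param score Minimum bitscore.
#' @return A condition node (class `bgc_condition`).
#' @name conditions
NULL

new_condition <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "bgc_condition")
}

#' @rdname conditions
#' @export
cond_profile <- function(profile_name) new_condition("PROFILE", profile_name = profile_name)

#' @rdname conditions
#' @export
cond_and <- function(...) {
  children <- list(...)
  if (length(children) < 2) stop("AND requires at least 2 children")
  new_condition("AND", children = children)
}

#' @rdname conditions
#' @export
cond_or <- function(...) {
  children <- list(...)
  if (length(children) < 2) stop("OR requires at least 2 children")
  new_condition("OR", children = children)
}

#' @rdname conditions
#' @export
cond_not <- function(x) new_condition("NOT", children = list(x))

#' @rdname conditions
#' @export
cond_minimum <- function(count, profiles) {
  if (count < 1) stop("minimum() count must be >= 1")
  new_condition("MINIMUM", count = as.integer(count), profiles = profiles)
}

#' @rdname conditions
#' @export
cond_minscore <- function(profile_name, score) {
  new_condition("MINSCORE", profile_name = profile_name, score = as.numeric(score))
}

#' Render a condition tree as DSL text
#' @param node A `bgc_condition`.
#' @return A character scalar.
#' @export
format_condition <- function(node) {
  switch(node$kind,
    PROFILE = node$profile_name,
    MINSCORE = sprintf("minscore(%s, %g)", node$profile_name, node$score),
    MINIMUM = sprintf("minimum(%d, [%s])", node$count,
                      paste(node$profiles, collapse = ", ")),
    NOT = sprintf("not %s", format_condition(node$children[[1]])),
    AND = paste(vapply(node$children, function(ch) {
      s <- format_condition(ch)
      if (ch$kind == "OR") paste0("(", s, ")") else s
    }, character(1)), collapse = " and "),
    OR = paste(vapply(node$children, format_condition, character(1)),
               collapse = " or "),
    stop("unknown condition kind: ", node$kind)
  )
}

#' @export
print.bgc_condition <- function(x, ...) {
  cat(format_condition(x), "\n")
  invisible(x)
}

# ---- tokenizer -------------------------------------------------------------

tokenize_rules <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  tokens <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    pos <- 1L
    n <- nchar(line)
    while (pos <= n) {
      ch <- substr(line, pos, pos)
      if (grepl("^\\s$", ch)) { pos <- pos + 1L; next }
      if (ch == "#") break  # comment to end of line
      if (ch %in% c("(", ")", "[", "]", ",")) {
        tokens[[length(tokens) + 1L]] <- list(type = ch, value = ch,
                                              line = ln, col = pos)
        pos <- pos + 1L
        next
      }
      if (ch == '"') {
        rest <- substr(line, pos + 1L, n)
        close <- regexpr('"', rest, fixed = TRUE)
        if (close < 0) {
          stop(sprintf("rule parse error at line %d, column %d: unterminated string",
                       ln, pos))
        }
        tokens[[length(tokens) + 1L]] <- list(
          type = "WORD", value = substr(rest, 1, close - 1L), line = ln, col = pos)
        pos <- pos + close + 1L
        next
      }
      m <- regexpr("^[A-Za-z0-9_.+-]+", substr(line, pos, n))
      if (m[1] == 1) {
        word <- regmatches(substr(line, pos, n), m)
        type <- if (grepl("^[0-9.]+$", word)) "NUMBER" else "WORD"
        tokens[[length(tokens) + 1L]] <- list(type = type, value = word,
                                              line = ln, col = pos)
        pos <- pos + attr(m, "match.length")
        next
      }
      stop(sprintf("rule parse error at line %d, column %d: unexpected character '%s'",
                   ln, pos, ch))
    }
  }
  tokens
}

# ---- parser ----------------------------------------------------------------

rule_parser <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env
}

peek_tok <- function(p) if (p$i <= length(p$tokens)) p$tokens[[p$i]] else NULL
next_tok <- function(p) { t <- peek_tok(p); if (!is.null(t)) p$last <- t; p$i <- p$i + 1L; t }

tok_error <- function(tok, msg, p = NULL) {
  if (is.null(tok) && !is.null(p) && !is.null(p$last)) {
    stop(sprintf("rule parse error at line %d, column %d: %s at end of input",
                 p$last$line, p$last$col, msg))
  }
  if (is.null(tok)) stop(sprintf("rule parse error at end of input: %s", msg))
  stop(sprintf("rule parse error at line %d, column %d: %s (near '%s')",
               tok$line, tok$col, msg, tok$value))
}

expect_word <- function(p, word) {
  tok <- next_tok(p)
  if (is.null(tok) || tok$type != "WORD" || tok$value != word) {
    tok_error(tok, paste0("expected '", word, "'"), p)
  }
  tok
}

expect_type <- function(p, type) {
  tok <- next_tok(p)
  if (is.null(tok) || tok$type != type) tok_error(tok, paste0("expected ", type), p)
  tok
}

parse_number <- function(p) {
  tok <- expect_type(p, "NUMBER")
  as.numeric(tok$value)
}

rule_keywords <- c("RULE", "CATEGORY", "CUTOFF", "NEIGHBOURHOOD",
                   "CONDITIONS", "EXTENDS")

at_keyword <- function(p) {
  tok <- peek_tok(p)
  !is.null(tok) && tok$type == "WORD" && tok$value %in% rule_keywords
}

parse_expr <- function(p) {
  left <- parse_and(p)
  repeat {
    tok <- peek_tok(p)
    if (is.null(tok) || tok$type != "WORD" || tok$value != "or") break
    next_tok(p)
    right <- parse_and(p)
    left <- if (left$kind == "OR") {
      new_condition("OR", children = c(left$children, list(right)))
    } else {
      cond_or(left, right)
    }
  }
  left
}

parse_and <- function(p) {
  left <- parse_unary(p)
  repeat {
    tok <- peek_tok(p)
    if (is.null(tok) || tok$type != "WORD" || tok$value != "and") break
    next_tok(p)
    right <- parse_unary(p)
    left <- if (left$kind == "AND") {
      new_condition("AND", children = c(left$children, list(right)))
    } else {
      cond_and(left, right)
    }
  }
  left
}

parse_unary <- function(p) {
  tok <- peek_tok(p)
  if (!is.null(tok) && tok$type == "WORD" && tok$value == "not") {
    next_tok(p)
    return(cond_not(parse_unary(p)))
  }
  parse_primary(p)
}

parse_primary <- function(p) {
  tok <- next_tok(p)
  if (is.null(tok)) tok_error(tok, "expected a condition", p)
  if (tok$type == "(") {
    inner <- parse_expr(p)
    close <- next_tok(p)
    if (is.null(close) || close$type != ")") tok_error(close, "expected ')'", p)
    return(inner)
  }
  if (tok$type != "WORD") tok_error(tok, "expected a profile name or function")
  if (tok$value == "minimum") {
    expect_type(p, "(")
    count <- parse_number(p)
    expect_type(p, ",")
    expect_type(p, "[")
    profiles <- character()
    repeat {
      w <- next_tok(p)
      if (is.null(w) || !w$type %in% c("WORD", "NUMBER")) {
        tok_error(w, "expected a profile name in minimum() list")
      }
      profiles <- c(profiles, w$value)
      sep <- next_tok(p)
      if (is.null(sep)) tok_error(sep, "expected ',' or ']'", p)
      if (sep$type == "]") break
      if (sep$type != ",") tok_error(sep, "expected ',' or ']'")
    }
    expect_type(p, ")")
    return(cond_minimum(count, profiles))
  }
  if (tok$value == "minscore") {
    expect_type(p, "(")
    prof <- expect_type(p, "WORD")
    expect_type(p, ",")
    score <- parse_number(p)
    expect_type(p, ")")
    return(cond_minscore(prof$value, score))
  }
  if (tok$value %in% c("and", "or", "not") || tok$value %in% rule_keywords) {
    tok_error(tok, "expected a condition")
  }
  cond_profile(tok$value)
}

#' Parse detection rules from DSL text
#'
#' Each rule block is `RULE <name> CATEGORY <category> CUTOFF <kb>
#' NEIGHBOURHOOD <kb> CONDITIONS <expr>` with an optional trailing
#' `EXTENDS <expr>`. Distances are written in kilobases and stored in
#' nucleotides. `#` starts a comment. Operator precedence in expressions
#' is `not` over `and` over `or`.
#'
#' @param text DSL source as a character scalar (or vector of lines).
#' @return A list of `bgc_rule` objects.
#' @export
parse_rules <- function(text) {
  text <- paste(text, collapse = "\n")
  p <- rule_parser(tokenize_rules(text))
  rules <- list()
  while (!is.null(peek_tok(p))) {
    expect_word(p, "RULE")
    name <- expect_type(p, "WORD")$value
    expect_word(p, "CATEGORY")
    category <- expect_type(p, "WORD")$value
    expect_word(p, "CUTOFF")
    cutoff_kb <- parse_number(p)
    expect_word(p, "NEIGHBOURHOOD")
    neighbourhood_kb <- parse_number(p)
    expect_word(p, "CONDITIONS")
    conditions <- parse_expr(p)
    extends <- NULL
    tok <- peek_tok(p)
    if (!is.null(tok) && tok$type == "WORD" && tok$value == "EXTENDS") {
      next_tok(p)
      extends <- parse_expr(p)
    }
    if (cutoff_kb <= 0) stop("rule '", name, "': CUTOFF must be positive")
    if (neighbourhood_kb < 0) stop("rule '", name, "': NEIGHBOURHOOD must be >= 0")
    if (name %in% vapply(rules, function(r) r$rule_name, character(1))) {
      stop("duplicate rule name '", name, "'")
    }
    rules[[length(rules) + 1L]] <- structure(
      list(rule_name = name, category = category,
           cutoff_nt = as.integer(round(cutoff_kb * 1000)),
           neighbourhood_nt = as.integer(round(neighbourhood_kb * 1000)),
           conditions = conditions, extends = extends),
      class = "bgc_rule"
    )
  }
  rules
}

#' Read detection rules from a file
#' @param path Path to a rule DSL file.
#' @return A list of `bgc_rule` objects.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("no such rules file: ", path)
  parse_rules(readLines(path, warn = FALSE))
}

#' @export
print.bgc_rule <- function(x, ...) {
  cat(sprintf("RULE %s CATEGORY %s CUTOFF %g NEIGHBOURHOOD %g\n",
              x$rule_name, x$category, x$cutoff_nt / 1000,
              x$neighbourhood_nt / 1000))
  cat("  CONDITIONS", format_condition(x$conditions), "\n")
  if (!is.null(x$extends)) cat("  EXTENDS", format_condition(x$extends), "\n")
  invisible(x)
}

# ---- evaluation ------------------------------------------------------------

#' Evaluate a condition over a set of hits
#'
#' `PROFILE` is true iff at least one hit to that profile exists;
#' `minimum(n, L)` iff hits cover at least `n` distinct profiles of `L`;
#' `minscore(p, s)` iff some hit to `p` scores at least `s` bits. A
#' profile named in a condition but absent from the hit set simply never
#' matches.
#'
#' @param node A `bgc_condition`.
#' @param hits Tibble with at least `profile_name` and `bitscore` columns.
#' @return Logical scalar.
#' @export
evaluate_condition <- function(node, hits) {
  switch(node$kind,
    PROFILE = node$profile_name %in% hits$profile_name,
    MINSCORE = any(hits$profile_name == node$profile_name &
                     hits$bitscore >= node$score),
    MINIMUM = length(intersect(node$profiles, unique(hits$profile_name))) >= node$count,
    NOT = !evaluate_condition(node$children[[1]], hits),
    AND = all(vapply(node$children, evaluate_condition, logical(1), hits = hits)),
    OR = any(vapply(node$children, evaluate_condition, logical(1), hits = hits)),
    stop("unknown condition kind: ", node$kind)
  )
}

# Which hits are marked "core" by a condition tree: each individually
# satisfied atomic condition marks the hits that satisfy it (for minscore,
# only hits reaching the score; for minimum, hits to the listed profiles).
# Nothing under a NOT marks cores. Returns a logical vector over hit rows.
satisfied_core_hits <- function(node, hits) {
  none <- rep(FALSE, nrow(hits))
  switch(node$kind,
    PROFILE = if (evaluate_condition(node, hits)) {
      hits$profile_name == node$profile_name
    } else none,
    MINSCORE = if (evaluate_condition(node, hits)) {
      hits$profile_name == node$profile_name & hits$bitscore >= node$score
    } else none,
    MINIMUM = if (evaluate_condition(node, hits)) {
      hits$profile_name %in% node$profiles
    } else none,
    NOT = none,
    AND = ,
    OR = Reduce(`|`, lapply(node$children, satisfied_core_hits, hits = hits), none),
    stop("unknown condition kind: ", node$kind)
  )
}

#' Profiles mentioned anywhere in a condition tree
#' @param node A `bgc_condition`.
#' @return Character vector of profile names.
#' @export
condition_profiles <- function(node) {
  switch(node$kind,
    PROFILE = ,
    MINSCORE = node$profile_name,
    MINIMUM = node$profiles,
    NOT = ,
    AND = ,
    OR = unique(unlist(lapply(node$children, condition_profiles))),
    stop("unknown condition kind: ", node$kind)
  )
}

# All profiles a rule can react to (conditions plus EXTENDS).
rule_profiles <- function(rule) {
  unique(c(condition_profiles(rule$conditions),
           if (!is.null(rule$extends)) condition_profiles(rule$extends)))
}
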