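# GPR (gene-protein-reaction) boolean rules: tokenizer, recursive-descent
# parser and evaluation under gene knockouts. Grammar:
#   expr := term ("or" term)* ; term := factor ("and" factor)* ;
#   factor := gene | "(" expr ")"

.gpr_tokens <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[toks != ""]
}

.gpr_parse <- function(tokens) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() { t <- tokens[pos]; pos <<- pos + 1L; t }
  factor <- function() {
    t <- take()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule")
    if (t == "(") {
      e <- expr()
      if (!identical(peek(), ")")) stop("GPR parse error: missing ')'")
      take()
      return(e)
    }
    if (t %in% c(")", "and", "or", "AND", "OR")) stop("GPR parse error near '", t, "'")
    list(type = "gene", id = t)
  }
  term <- function() {
    args <- list(factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(factor()))
    }
    if (length(args) == 1) args[[1]] else list(type = "and", args = args)
  }
  expr <- function() {
    args <- list(term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(term()))
    }
    if (length(args) == 1) args[[1]] else list(type = "or", args = args)
  }
  out <- expr()
  if (!is.na(peek())) stop("GPR parse error: trailing tokens")
  out
}

.gpr_eval_node <- function(node, knocked) {
  switch(node$type,
         gene = !(node$id %in% knocked),
         and = all(vapply(node$args, .gpr_eval_node, logical(1), knocked = knocked)),
         or = any(vapply(node$args, .gpr_eval_node, logical(1), knocked = knocked)),
         stop("unknown GPR node type"))
}

#' Evaluate a GPR rule under a set of gene knockouts
#'
#' @param rule GPR string, e.g. `"g1 and (g2 or g3)"`; the empty string means
#'   no gene requirement and always evaluates `TRUE`.
#' @param knocked character vector of knocked-out gene ids.
#' @return `TRUE` if the reaction can still be catalysed.
#' @export
gpr_eval <- function(rule, knocked = character(0)) {
  rule <- trimws(rule)
  if (rule == "") return(TRUE)
  .gpr_eval_node(.gpr_parse(.gpr_tokens(rule)), knocked)
}

#' Apply single- or multi-gene knockouts to a model
#'
#' Reactions whose GPR rule evaluates to `FALSE` under the knockout get
#' bounds (0, 0). Genes without associated reactions are legal and have no
#' effect.
#' @param model a `metabolic_model`.
#' @param genes character vector of gene ids to knock out.
#' @return the constrained `metabolic_model`.
#' @export
knockout_genes <- function(model, genes) {
  if (!length(genes)) return(model)
  hit <- vapply(model$gpr, function(r) !gpr_eval(r, genes), logical(1))
  model$lb[hit] <- 0
  model$ub[hit] <- 0
  model
}
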