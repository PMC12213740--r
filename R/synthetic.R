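# Seedable generator of triage-like corpora.
#
# The generator emulates the statistical shape of a real emergency-triage
# text collection: 11 departments with deliberately imbalanced counts, a
# mean document length of 92 whitespace words, department-specific local
# keyword cues (symptom phrases) and long-range contextual cues, plus a
# configurable rate of cross-department distractor phrases.

DEPT_COUNTS <- c(
  urology = 10000, dermatology = 3000, gynecology = 1000,
  cardiology = 1300, otolaryngology = 1100, gastroenterology = 1400,
  pediatrics = 2000, pulmonology = 2300, endocrinology = 1300,
  neurology = 1300, other = 3000
)

DEPT_KEYWORDS <- list(
  urology = c("burning urination", "blood in urine", "frequent urination",
              "flank pain", "difficulty passing urine", "kidney stone pain"),
  dermatology = c("itchy rash", "red skin patches", "scaly lesions",
                  "hives on arms", "peeling skin", "persistent acne"),
  gynecology = c("irregular periods", "pelvic cramping", "heavy bleeding",
                 "missed period", "ovarian pain", "vaginal discharge"),
  cardiology = c("chest pain", "heart palpitations", "pressure in chest",
                 "racing heartbeat", "pain radiating to arm",
                 "shortness of breath on exertion"),
  otolaryngology = c("sore throat", "ear pain", "blocked nose",
                     "ringing in ears", "hoarse voice", "painful swallowing"),
  gastroenterology = c("stomach cramps", "acid reflux", "persistent nausea",
                       "black stools", "bloating after meals",
                       "upper abdominal pain"),
  pediatrics = c("child with fever", "infant not feeding", "toddler coughing",
                 "child pulling at ear", "baby with diarrhea",
                 "child refusing to walk"),
  pulmonology = c("persistent cough", "wheezing at night", "coughing up phlegm",
                  "tight chest when breathing", "breathless climbing stairs",
                  "dry hacking cough"),
  endocrinology = c("excessive thirst", "unexplained weight loss",
                    "constant fatigue", "heat intolerance",
                    "swelling in neck", "trembling hands"),
  neurology = c("throbbing headache", "numbness in fingers", "dizzy spells",
                "blurred vision episodes", "tingling down one side",
                "memory lapses"),
  other = c("general malaise", "feeling run down", "mild discomfort",
            "vague aches", "trouble sleeping", "loss of appetite")
)

DEPT_TEMPLATES <- c(
  "patient reports {kw} starting several days ago",
  "presents with {kw} that has been getting worse",
  "complains of {kw} especially in the evening",
  "describes {kw} which improves after resting",
  "came in today because of {kw} and is worried",
  "states the {kw} began suddenly last night",
  "mentions {kw} on and off for about a week",
  "the main concern is {kw} with no relief from medication"
)

FILLER_CLAUSES <- c(
  "no fever was recorded at home",
  "appetite has been mostly normal",
  "denies any recent travel or contact with sick people",
  "has not taken any new medication recently",
  "sleep has been somewhat disturbed",
  "reports drinking plenty of fluids",
  "no previous history of a similar episode",
  "family history is unremarkable",
  "works long hours and feels stressed",
  "symptoms do not wake the patient at night",
  "tried over the counter remedies without effect",
  "otherwise feels generally well",
  "no known allergies to medication",
  "was seen by a pharmacist earlier this week",
  "the episode lasted for several minutes",
  "nothing seems to make it better or worse",
  "has an appointment with the family doctor next month",
  "similar complaints occurred two years ago and resolved",
  "lives alone and manages daily activities independently",
  "asks whether any tests will be needed"
)

#' Default department lexicons
#'
#' One lexicon per department: class name, symptom keyword phrases (local
#' cues), sentence templates (contextual cues), and the number of documents
#' to generate. Counts follow the deliberately imbalanced department mix of
#' a real triage collection (urology 10,000 down to gynecology 1,000),
#' multiplied by `scale`.
#'
#' @param scale multiplier on the full-scale counts; the default 0.01 yields
#'   a 277-document corpus suitable for tests and demos.
#' @return List of lexicons, each `list(department, keywords, templates, count)`.
#' @export
default_lexicons <- function(scale = 0.01) {
  lapply(names(DEPT_COUNTS), function(d) {
    list(department = d,
         keywords = DEPT_KEYWORDS[[d]],
         templates = DEPT_TEMPLATES,
         count = as.integer(round(DEPT_COUNTS[[d]] * scale)))
  })
}

#' Generator configuration
#'
#' @param lexicons list of department lexicons (see [default_lexicons()]).
#' @param target_mean_length target mean document length in whitespace words.
#' @param length_dispersion negative-binomial `size` parameter governing
#'   length over-dispersion (smaller = more dispersed).
#' @param noise_rate probability that a document receives one distractor
#'   phrase drawn from another department's keywords.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `tf_genconfig` list.
#' @export
gen_config <- function(lexicons = default_lexicons(),
                       target_mean_length = 92,
                       length_dispersion = 30,
                       noise_rate = 0.05,
                       seed = 0L) {
  stopifnot(target_mean_length > 0, noise_rate >= 0, noise_rate <= 1)
  structure(list(lexicons = lexicons,
                 target_mean_length = target_mean_length,
                 length_dispersion = length_dispersion,
                 noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "tf_genconfig")
}

# words of a phrase/sentence
.words <- function(x) strsplit(x, " ", fixed = TRUE)[[1]]

#' Generate a synthetic triage corpus
#'
#' Per-department document counts match the configuration exactly (counts
#' are not sampled). Each document opens with template sentences carrying
#' the department's keyword cues, continues with neutral filler clauses,
#' and is trimmed to a per-document target length drawn from a truncated
#' negative-binomial around the configured mean. With probability
#' `noise_rate` one distractor phrase from another department is injected.
#'
#' @param config a `tf_genconfig` (default [gen_config()]).
#' @return A `tf_corpus`.
#' @export
generate_corpus <- function(config = gen_config()) {
  if (length(config$lexicons) == 0L) stop("empty lexicon list")
  rng <- local_rng(config$seed)
  dept_names <- vapply(config$lexicons, function(l) l$department, "")
  ids <- character(0); texts <- character(0); labels <- character(0)
  for (li in seq_along(config$lexicons)) {
    lex <- config$lexicons[[li]]
    if (length(lex$keywords) == 0L) stop("lexicon has no keywords: ", lex$department)
    cnt <- lex$count
    if (cnt == 0L) next
    others <- setdiff(seq_along(config$lexicons), li)
    for (i in seq_len(cnt)) {
      target <- max(20L, rng$rnbinom_mu(1L, mu = config$target_mean_length,
                                        size = config$length_dispersion))
      words <- character(0)
      n_lead <- 1L + (rng$runif(1) < 0.5)   # 1-2 keyword-bearing sentences
      for (s in seq_len(n_lead)) {
        tpl <- lex$templates[rng$sample_int(length(lex$templates), 1L)]
        kw <- lex$keywords[rng$sample_int(length(lex$keywords), 1L)]
        words <- c(words, .words(sub("{kw}", kw, tpl, fixed = TRUE)))
      }
      if (length(others) && rng$runif(1) < config$noise_rate) {
        olex <- config$lexicons[[others[rng$sample_int(length(others), 1L)]]]
        okw <- olex$keywords[rng$sample_int(length(olex$keywords), 1L)]
        words <- c(words, "also", "mentions", .words(okw), "in", "passing")
      }
      while (length(words) < target) {
        fc <- FILLER_CLAUSES[rng$sample_int(length(FILLER_CLAUSES), 1L)]
        words <- c(words, .words(fc))
      }
      words <- words[seq_len(target)]
      ids <- c(ids, sprintf("%s_%05d", lex$department, i))
      texts <- c(texts, paste(words, collapse = " "))
      labels <- c(labels, lex$department)
    }
  }
  if (length(ids) == 0L)
    return(new_corpus(character(0), character(0), character(0)))
  new_corpus(ids, texts, labels)
}

# probe vocabulary: neutral filler words disjoint from all cue tokens
PROBE_FILLER <- c("patient", "reports", "ongoing", "discomfort", "since",
                  "yesterday", "morning", "without", "clear", "cause",
                  "generally", "stable", "condition", "noted", "today",
                  "routine", "review", "planned", "soon", "thanks")

LOCAL_PROBE_KEYS <- c(cardio = "palpitations", neuro = "migraine")
GLOBAL_PROBE_MARKERS <- c("exertion", "resting")

#' Generate a channel-preference probe corpus
#'
#' `kind = "local"`: two classes separable by a single class-unique keyword
#' embedded at a random position in class-neutral filler — solvable by a
#' local n-gram detector.
#'
#' `kind = "global"`: two classes distinguished only by the relative order
#' of two marker words separated by more than any convolution kernel width;
#' each document pair is token-identical up to the marker swap, so the two
#' classes have exactly equal unigram statistics and only an order-aware
#' (attention) feature can separate them.
#'
#' @param kind `"local"` or `"global"`.
#' @param n_per_class documents per class (>= 1).
#' @param seed integer seed.
#' @param gap for the global probe, filler tokens between the two markers
#'   (must exceed the widest CNN kernel; default 7).
#' @return A `tf_corpus` with two classes.
#' @export
generate_probe <- function(kind = c("local", "global"), n_per_class, seed = 0L,
                           gap = 7L) {
  kind <- match.arg(kind)
  stopifnot(n_per_class >= 1)
  rng <- local_rng(seed)
  ids <- character(0); texts <- character(0); labels <- character(0)
  if (kind == "local") {
    classes <- names(LOCAL_PROBE_KEYS)
    for (cl in classes) {
      kw <- LOCAL_PROBE_KEYS[[cl]]
      for (i in seq_len(n_per_class)) {
        n_fill <- 11L + rng$sample_int(4L, 1L)
        fill <- PROBE_FILLER[rng$sample_int(length(PROBE_FILLER), n_fill,
                                            replace = TRUE)]
        pos <- rng$sample_int(n_fill + 1L, 1L)
        words <- append(fill, kw, after = pos - 1L)
        ids <- c(ids, sprintf("%s_%05d", cl, i))
        texts <- c(texts, paste(words, collapse = " "))
        labels <- c(labels, cl)
      }
    }
  } else {
    m1 <- GLOBAL_PROBE_MARKERS[1]; m2 <- GLOBAL_PROBE_MARKERS[2]
    for (i in seq_len(n_per_class)) {
      # prefix length varies widely and the suffix is complementary, so the
      # markers' absolute positions are nearly uninformative about the
      # class: only the relative order (spanning > kernel width) decides.
      n_pre <- 1L + rng$sample_int(25L, 1L)
      n_suf <- 28L - n_pre
      pre <- PROBE_FILLER[rng$sample_int(length(PROBE_FILLER), n_pre, replace = TRUE)]
      mid <- PROBE_FILLER[rng$sample_int(length(PROBE_FILLER), gap, replace = TRUE)]
      suf <- PROBE_FILLER[rng$sample_int(length(PROBE_FILLER), n_suf, replace = TRUE)]
      ids <- c(ids, sprintf("orderA_%05d", i), sprintf("orderB_%05d", i))
      texts <- c(texts,
                 paste(c(pre, m1, mid, m2, suf), collapse = " "),
                 paste(c(pre, m2, mid, m1, suf), collapse = " "))
      labels <- c(labels, "orderA", "orderB")
    }
  }
  new_corpus(ids, texts, labels)
}

#' Read department lexicons from a YAML file
#'
#' The file holds a list of entries with keys `department`, `keywords`,
#' `templates` (optional; defaults to the built-in templates) and `count`.
#'
#' @param path YAML file path.
#' @return List of lexicons usable in [gen_config()].
#' @export
read_lexicons <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(l) {
    stopifnot(!is.null(l$department), !is.null(l$keywords))
    list(department = l$department,
         keywords = unlist(l$keywords),
         templates = unlist(l$templates %||% DEPT_TEMPLATES),
         count = as.integer(l$count %||% 0L))
  })
}
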