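---
title: "Architecture and design of the distributed-analytics sandbox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Architecture and design of the distributed-analytics sandbox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwdsandbox)
```

## The problem and the trust model

The package implements a sandbox for *distributed analytics* on hospital
data: an external researcher never receives patient-level rows; instead the
analysis is shipped into the hospital trust zone, executed next to the
data, and only aggregate results travel back. Three properties drive every
design choice:

1. **Mediation** — a single component (the proxy) owns all communication
   between the outside world and the data. The external client can only
   publish request files and read what the proxy chooses to deliver.
2. **Pull-only ingress** — the proxy *polls* the client channel; nothing
   outside the trust zone ever opens a connection inward. This is why the
   job protocol is a pair of XML files (a master table plus one detail file
   per job) that the client writes and the proxy reads, rather than an RPC
   the client invokes.
3. **Accountability** — every request and result is hash-notarised in an
   append-only ledger before/as it happens, and a result is only
   *officially issued* after both the platform and the user have digitally
   signed it. Neither side can later deny what was asked or what was
   returned.

## Components

A deployment (`sandbox_local()`) wires six agents together:

| Agent | Role |
|---|---|
| GUI channel | directory-backed protocol endpoint; records every delivered byte |
| Proxy | polls channels, authorises, resolves data/algorithms, dispatches tokens, routes results |
| Processor(s) | black-box executors watching input folders |
| permAgent | users, groups, items, grants, ticketed sessions |
| Notary | off-chain store + hash-chained ledger + dual signatures |
| Scheduler | periodic task list with exactly-once firing |

The proxy and processors share a filesystem (token drop-off and pick-up by
folder convention); the channel endpoint is a transport *contract* — the
built-in implementation is a directory the proxy polls, which preserves the
protocol files bit-exactly and lets a deterministic single-process test
drive both sides. An HTTP transport can be substituted behind the same
surface without touching the protocol.

## The token

A task travels as a zip archive with a fixed-name `descriptor.xml` member
(versioned with a `format_version` attribute; unknown elements are ignored
for forward compatibility) plus optional payload members. The descriptor
carries: job and user identity, exactly one algorithm reference (a script
member inside the archive, a locally loaded container image name, or a
locator into the local algorithm repository), an optional datamart
reference, the field→role map (`input`/`target`), string-valued run
settings, the notarise/sign flags, an optional cadence, and an ISO-8601
UTC timestamp. Serialisation is lossless: `parse_token(build_token(d, p))`
reproduces `d` and `p` exactly, which the suite checks property-style over
hundreds of random descriptors.

Payload member paths are validated before archiving — relative, unique, no
`..` components — so no token can ever write outside its extraction root.
The executor reports outcomes as an *output token* (`result.xml` plus
`results/` and `logs/` members); a failure token must carry at least one
log member, so failures are always diagnosable upstream.

## Execution model

Each processor polls its input folders and claims a token by an atomic
rename into a per-processor `processing/` directory — the token visibly
disappears from the input folder, and two watchers can never double-claim
one file. Claimed work is archived to `done/` after execution, so claimed
tokens and output tokens stay in one-to-one correspondence even for corrupt
archives (which yield a failure token carrying the parse error).

Executions run as background subprocesses, at most `max_parallel` at a
time, each with its own log file; surplus tokens queue in claim order.
Polling (rather than filesystem event APIs) is the portable default and
makes tests deterministic. The backend timeout defaults to one hour
(shorter in tests); a timed-out job is killed and flagged as such in its
failure token.

Script backends are chosen by extension (`.R` → Rscript, `.py` → python,
`.sh` → sh). The container backend enforces the platform's certification
rule: only images previously loaded into the *local* image store run, an
absent image is refused outright and no remote pull is ever attempted. The
built-in store maps image names to entrypoint scripts executed in the job
workdir — a simulated OCI runner that keeps the refusal semantics honest;
wiring a real container engine in is an extension point, not a change to
the contract.

## Authorisation

Permissions attach *items* (datamarts, algorithms, explicit pairs) to users
or groups; group hierarchies are acyclic (checked on insert) and a user's
rights flow from the transitive closure of memberships and parents. Checks
fail closed: unknown items deny, dead tickets return `auth-required`
(distinct from denial, so clients know to re-authenticate), and the
1,000-triple oracle test compares every decision against independent
brute-force reachability.

A (datamart, algorithm) pair is allowed iff both items are allowed; if an
explicit pair item `pair:<dm>|<alg>` is registered the pair additionally
requires a grant on it. Registering a pair item therefore *restricts* the
pair — deny wins — which covers both readings of pair-level authorisation
(pure conjunction, or first-class pair grants) with one rule.

Sessions are 256-bit random URL-safe tickets with an 8-hour default TTL.
Local profiles store salted, iterated SHA-256 password hashes and compare
in constant time; unknown users burn the same hashing cost so failures are
indistinguishable. Other profile kinds (e.g. LDAP) are injectable
verifier callbacks. Durable IAM state persists to a single JSON file — an
embedded relational store would serve equally behind the same save/load
surface.

## Notarisation and the dual-signature workflow

`notarize()` hashes the artefact (SHA-256, recorded in the digest's
`algorithm_id` so the ledger is self-describing), writes the blob into a
content-addressed off-chain directory *first*, and then appends a ledger
entry — index, timestamp, payload digest, previous entry digest, and an
entry digest over the canonical serialisation of those fields. The genesis
entry links an all-zero predecessor. `verify_ledger()` re-reads the file
and recomputes every link, returning the earliest broken index; the
property suite confirms that any single-byte mutation of any entry or blob
is detected. A single-file chain cannot by itself prove the *absence* of
truncated tail entries, so the chain head digest is exposed for external
anchoring; within the append-only model a truncated file is a valid
prefix. The built-in ledger is one implementation of a pluggable contract —
a distributed ledger with real consensus would slot in behind the same
five operations.

The request is notarised *before* any token is built or deposited, with
metadata only (user, datamart, algorithm, timestamp — devoid of data); if
notarisation fails the job is held and retried, never silently executed
un-notarised. Results are notarised on arrival. For signed jobs the
workflow is a three-state machine per job: the platform signs the report
with its Ed25519 key (`issued → sandbox_signed`), the user verifies the
platform signature, countersigns the signed envelope with their own key
and uploads the signature (`→ countersigned`). A valid countersignature
stores and notarises all three report artefacts — initial, sandbox-signed,
countersigned — so a completed signed job always contributes exactly five
ledger entries (1 request + 1 result + 3 reports), the job's full
accountability chain. A forged countersignature is rejected with state
unchanged.

## Load balancing and monitoring

The proxy tracks forwarded/completed/failed counters per processor
(`ongoing = forwarded − completed − failed ≥ 0` after every event) and
assigns each token to a live-heartbeat processor with minimum ongoing
count, ties broken by least forwarded then lexical id — deterministic, and
within ±1 forwarded job for equal-duration workloads. Outputs are matched
to requests by job id embedded both in the descriptor and the output
filename; orphan outputs are quarantined and logged, never forwarded.

## Scheduler semantics

Cadences are fixed intervals (anchored at task creation) or daily UTC wall
times. `tick(now)` fires each active task at most once per due instant;
missed instants are *not* back-filled — after a clock jump over several due
points the task fires once and resumes from the next cadence point. The
choice reflects the workload: these are idempotent snapshot analyses, and
a catch-up burst after downtime would only produce near-duplicate results.
Failed trigger deliveries are retried on the next tick, duplicate-
suppressed by (task, due instant). `resume` after `freeze` re-anchors at
the next future cadence point; `removed` is terminal. The task list is
journaled to JSON so restarts do not lose schedules.

## Synthetic data: what it does and does not show

The fixture generators are deterministic under a seed (byte-identical CSV
output, which the suite asserts). The demo patient datamart draws age from
N(62, 12) rounded to years, sex F/M at 0.52/0.48, a continuous biomarker
from N(50, 10) and a uniform diagnosis date — plausible magnitudes for an
oncology cohort, chosen once as defaults. The OMOP-style subset is two
tables, `person(person_id, gender, year_of_birth)` and
`condition_occurrence(person_id, condition_concept_id, start_date)`, with
0–3 conditions per person and guaranteed referential integrity; full CDM
coverage is out of scope.

Every generated row carries a `row_sentinel` marker column. The mediation
property is asserted mechanically: after randomized multi-job runs the
entire recorded channel transcript is scanned for sentinel values, and the
toy algorithms emit only aggregates (means, counts, distinct-level counts —
never level values). Passing this shows the *plumbing* never leaks rows; it
deliberately does not claim semantic disclosure safety — a query so narrow
that its aggregate identifies a patient is a statistical-disclosure-control
problem outside this package's scope, and the natural place for a future
differential-privacy stage on the result path.

Cohort queries are conjunctions of typed predicates
(`=, ≠, <, ≤, >, ≥, in`), with an inner join on `person_id` for the
two-table case. Conjunctions keep the semantics decidable at a glance and
suffice to exercise the pipeline; OR/NOT would add power the platform's
tests do not need. Unknown fields and non-numeric literals against numeric
fields are errors, not silent empty results.

## Numerical and operational choices

- Timestamps are ISO-8601 UTC with microseconds throughout; event ordering
  in tests relies on monotone sequence numbers, not clock resolution.
- All time-dependent agents take an injectable clock; the scheduler and
  session-expiry tests run on a fake clock, processor subprocess deadlines
  use wall time.
- Default poll cadence is 2 s for free-running deployments; the test
  harness steps agents explicitly instead of sleeping.
- Test problem sizes (e.g. 20-job mediation runs, 50-token conservation
  runs, 1,000 IAM triples, 100 tamper mutations) were chosen to exercise
  concurrency and randomness meaningfully while keeping the default suite
  fast on one CPU.

## Known limitations

Single-institution by design: one proxy, local processors, no cross-
hospital federation. No disclosure control on result contents (see above).
The built-in ledger is tamper-evident, not consensus-backed; tail
truncation requires the external head-digest anchor. SQL connectors
(mysql/sqlserver/sasviya dialects) are contract stubs — only the CSV
connector ships. The channel transport is in-process/filesystem; HTTPS
deployment is an integration concern left to the operator.
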