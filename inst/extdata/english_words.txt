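# Common English and biomedical descriptive words used by the misspelling
# heuristic: a word absent from this list is treated as a gene/protein name.
a
about
above
absence
according
account
acid
acids
across
action
active
activity
addition
additional
affect
affected
affects
after
again
against
aggregation
all
allow
allows
almost
along
also
although
always
amino
among
amount
an
analysis
analyses
and
animal
animals
annotated
annotation
another
any
appear
appears
apparent
approach
are
area
around
array
as
assay
assays
assist
assists
associated
association
at
authors
available
bacteria
bacterial
bacterium
base
based
be
because
become
becomes
been
before
behavior
behaviour
being
below
between
binding
biological
biology
body
both
bound
broad
but
by
can
cannot
case
cases
cause
caused
causes
cell
cells
cellular
certain
change
changes
chaperone
chaperones
chapter
characterized
chemical
chromosome
class
clear
clearly
clone
cloned
close
cluster
coding
common
compared
comparison
component
components
composed
compound
concentration
conclusion
condition
conditions
confirm
confirmed
consider
considered
consistent
contain
contained
containing
contains
content
context
control
controlled
controls
copy
core
correct
correctly
corresponding
could
count
counted
culture
cultures
current
data
database
databases
day
days
decrease
decreased
defect
defective
defined
degradation
degree
deletion
demonstrate
demonstrated
dependent
depending
described
detail
detailed
detect
detected
detection
determine
determined
development
did
differ
difference
differences
different
direct
directly
discussed
disease
distinct
distribution
divergent
diverse
division
do
does
domain
done
down
downstream
due
during
each
early
effect
effects
efficiency
either
element
elements
eliminate
eliminated
encode
encoded
encodes
encoding
end
enhance
enhanced
enzymatic
enzyme
enzymes
essential
establish
established
estimate
estimated
evidence
evident
exact
examined
example
examples
excess
exhibit
exhibited
exist
existence
existing
experiment
experimental
experiments
exponential
extent
external
extract
extracted
extraction
factor
factors
family
feature
features
few
fewer
field
figure
final
finally
finding
findings
first
five
fold
folding
follow
followed
following
for
form
formation
formed
forms
found
four
fraction
frame
free
frequency
frequently
from
full
fully
function
functional
functions
further
fusion
future
general
generally
generate
generated
genetic
genome
genomic
give
given
gives
global
growth
growing
grown
had
half
has
have
having
heat
helix
help
helps
here
high
higher
highest
highly
host
how
however
human
hybrid
identical
identification
identified
identify
if
image
important
in
include
included
includes
including
increase
increased
increases
increasing
independent
independently
indicate
indicated
indicates
indicating
individual
induction
influence
information
inhibition
initial
initiation
insertion
inside
insight
insights
interact
interacting
interaction
interactions
interacts
internal
into
involve
involved
involves
is
isolate
isolated
isolates
it
its
itself
key
kinase
known
lack
lacking
large
larger
last
late
later
lead
leading
leads
least
length
less
level
levels
library
light
like
likely
limit
limited
line
lines
link
linked
list
literature
little
local
located
location
locus
long
longer
loss
low
lower
machinery
made
main
mainly
maintain
major
make
makes
manner
many
map
mapped
marker
mass
material
may
mean
measure
measured
measurement
mechanism
mechanisms
medium
member
members
membrane
method
methods
might
minor
misfolding
missing
model
models
moderate
modification
molecular
molecule
molecules
more
moreover
most
motif
much
multiple
must
mutant
mutants
mutation
mutations
name
named
names
native
nature
near
nearly
necessary
need
needed
negative
neither
network
networks
new
next
no
non
none
normal
not
notable
note
noted
novel
now
nuclear
number
numbers
observation
observations
observed
obtain
obtained
occur
occurred
occurs
of
off
often
on
once
one
only
onto
open
operon
or
order
organism
organisms
origin
original
other
others
our
out
outside
over
overall
overnight
own
pair
pairs
paper
papers
part
partial
particular
pathway
pathways
pattern
patterns
per
percent
performed
perhaps
period
phase
phenotype
phrase
physical
plant
plants
plasmid
play
plays
point
points
population
position
positive
possible
possibly
potential
predict
predicted
prediction
presence
present
presented
prevent
prevents
previous
previously
primary
prior
probable
probably
process
processes
processing
produce
produced
produces
product
products
profile
profiles
promoter
promoters
properties
property
propose
proposed
protein
proteins
provide
provided
provides
publication
published
putative
quality
question
range
rate
rates
rather
ratio
reaction
reactions
read
reading
receptor
recent
recently
recognition
recognize
recognized
reduce
reduced
reduction
reference
referenced
region
regions
related
relation
relations
relationship
relationships
relative
relevant
remain
remained
remains
remove
removed
replicate
replication
report
reported
reports
require
required
requires
research
residue
residues
respect
respectively
response
responses
responsible
rest
result
resulted
resulting
results
reveal
revealed
reveals
reverse
review
ribosome
rich
role
roles
same
sample
samples
scale
screen
screened
search
second
secondary
section
see
seen
segment
selected
selection
sensitive
sentence
sentences
separate
separated
sequence
sequences
series
set
sets
seven
several
shock
short
should
show
showed
shown
shows
signal
significant
significantly
similar
similarity
simple
since
single
site
sites
six
size
small
smaller
so
some
source
sources
species
specific
specificity
stable
stage
stages
standard
start
state
stated
states
stationary
strain
strains
stress
strong
strongly
structural
structure
structures
studied
studies
study
subject
subsequent
subset
substrate
substrates
subunit
such
suggest
suggested
suggesting
suggests
supplement
support
supported
suppressor
surface
synthesis
system
systems
table
take
taken
target
targets
technique
techniques
temperature
term
terminal
terms
test
tested
testing
tests
text
than
that
the
their
them
then
there
therefore
these
they
third
this
those
three
through
throughout
thus
time
times
tissue
tissues
to
together
total
toward
transcript
transcripts
transfer
translation
treatment
trial
true
two
type
types
typical
under
understand
understanding
undergoing
unique
unit
units
unknown
unlike
until
up
upon
upstream
use
used
uses
using
value
values
variable
variant
variants
variation
various
vector
version
very
via
view
wall
was
water
way
we
weak
well
were
what
when
where
whereas
whether
which
while
whose
wide
widely
wild
will
with
within
without
word
words
work
would
yeast
yield
zero
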