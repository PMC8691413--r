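# Built-in English word list for the dictionary-ratio language check.
# One word per line, lowercase. Deliberately small: common function words,
# everyday vocabulary, the toy-lexicon tokens, emoji short-name words, and
# the packaged taxonomy vocabulary.
the
be
to
of
and
a
an
in
that
have
has
had
i
it
for
not
no
yes
on
with
he
she
they
we
you
do
does
did
at
this
these
those
but
his
her
their
our
your
my
by
from
up
down
about
into
over
after
before
again
then
than
so
some
any
all
more
most
other
such
only
just
also
very
can
could
will
would
shall
should
may
might
must
as
if
or
because
while
when
where
why
how
what
who
whom
which
there
here
out
off
above
below
between
through
during
against
each
few
many
much
own
same
too
now
today
tomorrow
yesterday
never
always
often
sometimes
people
person
man
woman
child
children
friend
family
world
country
city
home
house
place
thing
things
way
time
year
years
day
days
week
month
hour
minute
life
hand
part
eye
eyes
face
work
news
story
word
words
number
group
problem
fact
truth
question
answer
right
left
new
old
big
small
long
short
high
low
early
late
young
little
large
next
last
first
second
third
really
still
even
back
think
thinks
thought
know
knows
knew
known
take
takes
took
see
sees
saw
seen
look
looks
looked
come
comes
came
want
wants
wanted
give
gives
gave
use
uses
used
find
finds
found
tell
tells
told
ask
asks
asked
seem
seems
feel
feels
felt
try
tries
tried
leave
leaves
call
calls
called
read
reads
say
says
said
get
gets
got
make
makes
made
go
goes
went
gone
keep
keeps
kept
let
lets
begin
began
show
shows
showed
hear
hears
heard
play
run
move
live
lives
lived
believe
believes
believed
hold
bring
brings
brought
write
writes
wrote
sit
stand
lose
lost
pay
meet
met
include
includes
continue
set
learn
learned
change
changes
changed
lead
leads
understand
understood
watch
watched
follow
follows
followed
stop
stopped
create
created
speak
spoke
spoken
share
shares
shared
post
posts
posted
comment
comments
thread
threads
report
reports
vote
votes
voted
jury
juror
jurors
flag
flags
flagged
remove
removed
keep
content
media
social
online
internet
platform
platforms
user
users
account
accounts
message
messages
health
doctor
doctors
nurse
hospital
medicine
vaccine
vaccines
vaccination
mask
masks
virus
viruses
variant
variants
pandemic
outbreak
disease
infection
infected
covid
corona
coronavirus
china
chinese
wuhan
india
indian
alpha
beta
delta
bioweapon
microchip
sars-cov-2
b.1.617
lab
science
scientist
scientists
study
studies
research
evidence
data
expert
experts
government
public
information
misinformation
cat
sat
dog
mat
okay
fine
decent
good
nice
happy
glad
great
lovely
wonderful
amazing
excellent
helpful
kind
hopeful
safe
true
calm
dull
poor
sad
bad
upset
angry
awful
terrible
horrible
disgusting
dreadful
horrific
useless
scary
dangerous
false
wrong
fear
hate
lie
lies
grinning
beaming
smiling
tears
joy
sweat
squinting
winking
heart
hearts
sunglasses
neutral
unamused
pensive
blowing
kiss
disappointed
enraged
crying
loudly
open
mouth
screaming
sleeping
medical
rolling
thermometer
thinking
clown
nauseated
facepalming
person
shrugging
thumbs
clapping
hands
flexed
biceps
fire
syringe
microbe
blue
red
broken
folded
rocket
warning
stay
wash
your
careful
trust
everyone
nobody
somebody
thanks
thank
please
welcome
sorry
agree
disagree
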