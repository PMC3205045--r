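a
about
above
add
added
after
again
air
all
almost
along
also
always
an
and
animal
another
answer
any
are
around
as
ask
at
away
back
be
because
been
before
began
begin
being
below
between
big
book
both
boy
but
by
call
came
can
car
carry
chair
change
children
city
clean
close
come
cooled
could
country
cut
day
did
different
dirty
do
does
down
dried
each
early
earth
eat
empty
end
enough
even
evening
every
example
eye
face
family
far
father
feet
few
filtered
find
first
follow
food
for
form
found
four
from
full
garden
get
girl
give
go
good
got
great
green
group
grow
had
hand
happy
hard
has
have
head
hear
heated
help
her
here
high
him
his
home
horse
house
how
idea
if
important
in
into
is
its
just
keep
kind
know
land
large
last
late
later
learn
leave
left
let
letter
light
like
line
list
little
live
long
look
made
make
man
many
may
me
mean
men
might
mile
miss
mixture
more
morning
most
mother
mountain
mouse
move
much
must
my
name
near
need
never
new
next
night
no
not
now
number
obtained
of
off
often
oil
old
on
once
one
only
open
or
other
our
out
over
overnight
own
page
paper
part
people
picture
place
plant
play
point
product
purple
put
quick
quiet
reaction
read
really
residue
right
river
run
said
same
saw
say
school
sea
second
see
seem
sentence
set
she
should
show
side
simple
slow
small
so
solution
some
something
sometimes
song
soon
sound
spell
start
still
stirred
stirring
stop
story
strong
study
such
summer
table
take
talk
tell
than
the
their
them
then
there
these
they
thing
think
this
those
thought
three
through
time
to
together
too
took
tree
try
turn
two
under
until
up
us
use
very
walk
want
was
washed
watch
water
way
we
weak
well
went
were
what
when
where
which
while
white
who
why
will
window
winter
with
without
word
work
world
would
write
year
yellow
yield
young
your
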